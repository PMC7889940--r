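#' Run configuration for the full analysis pipeline
#'
#' @param abundance_path long- or wide-format abundance CSV/TSV
#' @param meta_path sample metadata CSV/TSV
#' @param traits_path optional species trait CSV/TSV
#' @param layout abundance file layout ("long" or "wide")
#' @param out_dir output directory (created if absent)
#' @param pool_replicates sum replicate samples within sites first
#' @param integrate_strata then sum strata within sites
#' @param sqrt_transform square-root transform counts before Bray-Curtis
#' @param nmds_dims,nmds_restarts NMDS dimensions and restarts
#' @param n_perm permutations for PERMANOVA and post-hoc tests
#' @param seed integer seed recorded in every output's provenance
#' @param digits rounding applied to floating-point table output (full
#'   precision is kept in the JSON manifest)
#' @return list of class \code{run_config}
#' @export
run_config <- function(abundance_path, meta_path, traits_path = NULL,
                       layout = "long", out_dir = "benthoshare_out",
                       pool_replicates = TRUE, integrate_strata = TRUE,
                       sqrt_transform = TRUE, nmds_dims = 2,
                       nmds_restarts = 20, n_perm = 9999, seed = 1,
                       digits = 4) {
  cfg <- list(abundance_path = abundance_path, meta_path = meta_path,
              traits_path = traits_path, layout = layout, out_dir = out_dir,
              pool_replicates = pool_replicates,
              integrate_strata = integrate_strata,
              sqrt_transform = sqrt_transform, nmds_dims = nmds_dims,
              nmds_restarts = nmds_restarts, n_perm = n_perm,
              seed = as.integer(seed), digits = digits)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline run configuration from YAML
#' @param path YAML file whose fields are \code{\link{run_config}} arguments
#' @return a \code{run_config}
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  df
}

stage <- function(name, code) {
  message(sprintf("[%s] ...", name))
  tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full habitat-sharing analysis pipeline
#'
#' validate -> pool/integrate -> classify -> dominance -> functional ->
#' dissimilarity -> NMDS -> PERMANOVA -> reports. Every numeric table is
#' written to \code{out_dir} along with a JSON manifest recording the package
#' version, seed, parameters and headline numbers at full precision, so each
#' table is reproducible from the manifest alone.
#'
#' @param config a \code{run_config}
#' @return invisible list with all intermediate and final results
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dg <- config$digits
  outp <- function(f) file.path(config$out_dir, f)

  table <- stage("read", read_abundance(config$abundance_path, config$layout))
  meta <- stage("read", read_sample_meta(config$meta_path))
  traits <- if (!is.null(config$traits_path)) {
    stage("read", read_traits(config$traits_path))
  } else NULL
  stage("validate", validate_bundle(table, meta, traits))
  message(sprintf("[validate] %d samples x %d species", nrow(table), ncol(table)))

  if (config$pool_replicates) {
    res <- stage("pool", pool_replicates(table, meta))
    table <- res$table; meta <- res$meta
    message(sprintf("[pool] -> %d pooled samples", nrow(table)))
  }
  if (config$integrate_strata) {
    res <- stage("integrate", integrate_strata(table, meta))
    table <- res$table; meta <- res$meta
    message(sprintf("[integrate] -> %d site communities", nrow(table)))
  }

  times <- sort(unique(meta$time))
  sets_by_time <- lapply(times, function(tm) habitat_species_sets(table, meta, tm))
  names(sets_by_time) <- times
  cls_by_time <- lapply(sets_by_time, classify_species)

  sharing <- stage("classify", {
    do.call(rbind, lapply(times, function(tm) {
      s <- sharing_summary(sets_by_time[[tm]], cls_by_time[[tm]])
      cbind(time = tm, s)
    }))
  })
  write_delim_table(sharing, outp("sharing_summary.csv"))

  k_users <- stage("classify", {
    do.call(rbind, lapply(times, function(tm) {
      cl <- cls_by_time[[tm]]
      if (cl$n_habitats < 3) return(NULL)
      do.call(rbind, lapply(2:(cl$n_habitats - 1), function(k) {
        u <- k_habitat_users(cl, k)
        data.frame(time = tm, k = k, combination = names(u),
                   count = as.integer(u), stringsAsFactors = FALSE)
      }))
    }))
  })
  write_delim_table(k_users, outp("k_habitat_users.csv"))

  pairs <- stage("classify", {
    do.call(rbind, lapply(times, function(tm) {
      cbind(time = tm, pairwise_sharing(sets_by_time[[tm]]))
    }))
  })
  write_delim_table(round_df(pairs, dg), outp("pairwise_sharing.csv"))

  selections <- stage("dominance", select_abundant_all(table))
  dom_report <- selection_coverage_report(selections, meta)
  write_delim_table(round_df(dom_report, dg), outp("dominance_report.csv"))
  sel_long <- do.call(rbind, lapply(names(selections), function(s) {
    data.frame(sample_id = s, species_id = selections[[s]]$selected,
               count = selections[[s]]$selected_counts,
               stringsAsFactors = FALSE)
  }))
  write_delim_table(sel_long, outp("selected_species.csv"))

  functional <- NULL
  if (!is.null(traits)) {
    functional <- stage("functional", {
      lapply(c("feeding_type", "life_form"), function(f) {
        ft <- aggregate_by_trait(table, selections, traits, field = f)
        comp <- relative_composition(ft, by = "habitat_time", meta = meta)
        write_delim_table(
          data.frame(group = colnames(ft), t(unclass(ft)), check.names = FALSE),
          outp(paste0("functional_", f, ".csv")))
        write_delim_table(round_df(comp, dg),
                          outp(paste0("composition_", f, ".csv")))
        list(table = ft, composition = comp)
      })
    })
    names(functional) <- c("feeding_type", "life_form")
  }

  d_bc <- stage("dissim", bray_curtis(table, config$sqrt_transform))
  d_jac <- stage("dissim", jaccard_dissim(to_incidence(table)))
  write_dissimilarity(d_bc, outp("bray_curtis.csv"))
  write_dissimilarity(d_jac, outp("jaccard.csv"))

  ord <- stage("nmds", nmds(d_bc, k = config$nmds_dims,
                            n_restarts = config$nmds_restarts,
                            seed = config$seed))
  coords <- data.frame(sample_id = rownames(ord$points), ord$points,
                       check.names = FALSE)
  write_delim_table(round_df(coords, dg), outp("nmds_coordinates.csv"))

  perm <- stage("permanova", permanova(d_bc, meta,
                                       terms = c("habitat", "time"),
                                       interaction = length(unique(meta$time)) > 1,
                                       n_perm = config$n_perm,
                                       seed = config$seed))
  write_delim_table(round_df(as.data.frame(perm), dg), outp("permanova.csv"))

  pw <- NULL
  if (length(unique(meta$time)) >= 1 && length(unique(meta$habitat)) >= 2) {
    pw <- stage("pairwise", pairwise_permanova(d_bc, meta,
                                               n_perm = config$n_perm,
                                               seed = config$seed))
    write_delim_table(round_df(pw, dg), outp("pairwise_permanova.csv"))
  }

  params <- config[setdiff(names(config), "out_dir")]
  # record input files by name, not location, so identical runs produce
  # identical manifests wherever the inputs live
  for (pp in c("abundance_path", "meta_path", "traits_path")) {
    if (!is.null(params[[pp]])) params[[pp]] <- basename(params[[pp]])
  }
  manifest <- list(
    package = "benthoshare",
    version = as.character(utils::packageVersion("benthoshare")),
    seed = config$seed,
    parameters = params,
    n_samples = nrow(table),
    n_species = ncol(table),
    times = times,
    habitats = sort(unique(meta$habitat)),
    nmds = list(stress = ord$stress, accepted = ord$accepted,
                converged = ord$converged, best_restart = ord$best_restart),
    permanova = as.data.frame(perm),
    outputs = list.files(config$out_dir)
  )
  jsonlite::write_json(manifest, outp("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(table = table, meta = meta, traits = traits,
                 sets_by_time = sets_by_time, cls_by_time = cls_by_time,
                 sharing = sharing, k_users = k_users, pairs = pairs,
                 selections = selections, dominance = dom_report,
                 functional = functional, d_bray = d_bc, d_jaccard = d_jac,
                 nmds = ord, permanova = perm, pairwise = pw,
                 manifest = manifest))
}

#' Write a synthetic dataset in the pipeline's CSV formats
#'
#' @param dataset a \code{synthetic_dataset}
#' @param dir output directory
#' @return named character vector of written paths
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    abundance = file.path(dir, "abundance.csv"),
    meta = file.path(dir, "metadata.csv"),
    traits = file.path(dir, "traits.csv"),
    truth = file.path(dir, "truth.csv")
  )
  write_abundance(dataset$table, paths["abundance"], layout = "long")
  write_delim_table(as.data.frame(dataset$meta), paths["meta"])
  write_delim_table(as.data.frame(dataset$traits), paths["traits"])
  write_delim_table(dataset$truth, paths["truth"])
  paths
}
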