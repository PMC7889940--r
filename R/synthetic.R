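#' Configuration for the synthetic community generator
#'
#' Defines a multi-habitat, multi-season benthic survey with known ground
#' truth. Species are partitioned into a ubiquitous pool (present in every
#' habitat), habitat-endemic pools, and a shifting pool occupying random
#' habitat subsets of size 2..H-1 drawn with the given weights. Each species
#' gets a lognormal base abundance; expected counts are base abundance times
#' habitat-affinity indicator times multiplicative habitat/time effects, and
#' observed counts are Poisson draws thinned by the detection probability.
#' The defaults mirror a 4-habitat x 2-season x 5-site survey with a species
#' pool of roughly 250 and a category mix dominated by endemics.
#'
#' @param n_habitats number of habitats H (>= 2 when the shifting pool is
#'   nonempty)
#' @param n_times number of sampling times
#' @param sites_per_habitat sampling sites per habitat and time
#' @param n_common size of the ubiquitous pool
#' @param n_endemic_per_habitat endemic species per habitat
#' @param n_shifting size of the shifting pool
#' @param combo_size_weights probability weights for shifting combination
#'   sizes 2..H-1
#' @param meanlog,sdlog lognormal parameters of species base abundance per
#'   sample (right-skewed, sdlog ~ 1 is typical of community data)
#' @param effect_size multiplicative habitat effect applied to affected
#'   species (1 = null, no habitat signal beyond pool membership)
#' @param effect_prop proportion of species receiving the habitat effect
#' @param time_effect multiplicative effect of the second and later sampling
#'   times on affected species (1 = no seasonal signal)
#' @param detection detection probability thinning the Poisson counts
#' @param feeding_vocab,life_form_vocab trait vocabularies sampled uniformly
#' @param seed integer seed (mandatory: the generator has no hidden
#'   randomness)
#' @return a validated list of class \code{synthetic_config}
#' @export
synthetic_config <- function(n_habitats = 4, n_times = 2,
                             sites_per_habitat = 5,
                             n_common = 8, n_endemic_per_habitat = 35,
                             n_shifting = 100,
                             combo_size_weights = c(0.7, 0.3),
                             meanlog = 2, sdlog = 1,
                             effect_size = 1, effect_prop = 0.3,
                             time_effect = 1,
                             detection = 1,
                             feeding_vocab = c("Ca", "Dp", "Dt", "FS", "Gr",
                                               "He", "Om", "Sc", "Sy"),
                             life_form_vocab = c("BU", "FL", "PA", "SE", "TM"),
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_habitats >= 1, n_times >= 1, sites_per_habitat >= 1,
            n_common >= 0, n_endemic_per_habitat >= 0, n_shifting >= 0,
            detection >= 0, detection <= 1, effect_size > 0, time_effect > 0,
            effect_prop >= 0, effect_prop <= 1)
  if (n_shifting > 0 && n_habitats < 3) {
    stop("a nonempty shifting pool requires H >= 3 (combination sizes 2..H-1)",
         call. = FALSE)
  }
  n_species <- n_common + n_endemic_per_habitat * n_habitats + n_shifting
  if (n_species == 0L) stop("config yields zero species", call. = FALSE)
  cfg <- list(
    n_habitats = n_habitats, n_times = n_times,
    sites_per_habitat = sites_per_habitat,
    n_common = n_common, n_endemic_per_habitat = n_endemic_per_habitat,
    n_shifting = n_shifting, combo_size_weights = combo_size_weights,
    meanlog = meanlog, sdlog = sdlog,
    effect_size = effect_size, effect_prop = effect_prop,
    time_effect = time_effect, detection = detection,
    feeding_vocab = feeding_vocab, life_form_vocab = life_form_vocab,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Read a synthetic-generator configuration from YAML or JSON
#' @param path .yaml/.yml or .json file whose fields are
#'   \code{\link{synthetic_config}} arguments
#' @return a \code{synthetic_config}
#' @export
read_synthetic_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(synthetic_config, vals)
}

#' Generate a synthetic multi-habitat community dataset
#'
#' Deterministic given the config seed. Endemic species never occur outside
#' their habitat; ubiquitous species have positive expected abundance in every
#' habitat; shifting species occupy their assigned habitat subset. The truth
#' table records each species' generating category and habitat combination,
#' against which recovered classifications can be scored.
#'
#' @param config a \code{synthetic_config}
#' @return object of class \code{synthetic_dataset}: list with \code{table}
#'   (an \code{abundance_table}), \code{meta}, \code{traits}, \code{truth}
#'   (data.frame species_id, category, habitats) and \code{config}
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  H <- config$n_habitats
  habs <- paste0("H", seq_len(H))
  times <- paste0("T", seq_len(config$n_times))
  with_seed(config$seed, {
    # species pools and habitat affinities
    species <- character(0)
    affinity <- list()
    category <- character(0)
    if (config$n_common > 0) {
      ids <- sprintf("sp_common_%03d", seq_len(config$n_common))
      species <- c(species, ids)
      affinity <- c(affinity, rep(list(habs), config$n_common))
      category <- c(category, rep("common", config$n_common))
    }
    if (config$n_endemic_per_habitat > 0) {
      for (h in habs) {
        ids <- sprintf("sp_endemic_%s_%03d", h,
                       seq_len(config$n_endemic_per_habitat))
        species <- c(species, ids)
        affinity <- c(affinity, rep(list(h), config$n_endemic_per_habitat))
        category <- c(category, rep("endemic", config$n_endemic_per_habitat))
      }
    }
    if (config$n_shifting > 0) {
      sizes <- 2:(H - 1)
      w <- config$combo_size_weights
      if (length(w) != length(sizes)) {
        stop("combo_size_weights must have length H - 2", call. = FALSE)
      }
      ids <- sprintf("sp_shifting_%03d", seq_len(config$n_shifting))
      species <- c(species, ids)
      for (i in seq_len(config$n_shifting)) {
        k <- sample(sizes, 1, prob = w)
        affinity <- c(affinity, list(sort(sample(habs, k))))
      }
      category <- c(category, rep("shifting", config$n_shifting))
    }
    names(affinity) <- species
    S <- length(species)

    # lognormal base abundance; habitat/time effects on an affected subset
    lambda <- stats::rlnorm(S, meanlog = config$meanlog, sdlog = config$sdlog)
    affected <- stats::runif(S) < config$effect_prop
    boosted_hab <- vapply(seq_len(S), function(i) {
      if (affected[i]) sample(affinity[[i]], 1) else NA_character_
    }, character(1))

    sample_rows <- expand.grid(site = seq_len(config$sites_per_habitat),
                               time = times, habitat = habs,
                               stringsAsFactors = FALSE)
    sample_rows$sample_id <- sprintf("%s_%s_s%d", sample_rows$habitat,
                                     sample_rows$time, sample_rows$site)
    counts <- matrix(0, nrow = nrow(sample_rows), ncol = S,
                     dimnames = list(sample_rows$sample_id, species))
    for (r in seq_len(nrow(sample_rows))) {
      h <- sample_rows$habitat[r]
      tm <- sample_rows$time[r]
      mu <- lambda
      present <- vapply(affinity, function(a) h %in% a, logical(1))
      mu[!present] <- 0
      boost <- affected & !is.na(boosted_hab) & boosted_hab == h
      mu[boost] <- mu[boost] * config$effect_size
      if (tm != times[1]) {
        mu[affected] <- mu[affected] * config$time_effect
      }
      counts[r, ] <- stats::rpois(S, mu * config$detection)
    }

    traits <- trait_table(data.frame(
      species_id = species,
      feeding_type = sample(config$feeding_vocab, S, replace = TRUE),
      life_form = sample(config$life_form_vocab, S, replace = TRUE),
      stringsAsFactors = FALSE
    ), feeding_vocab = config$feeding_vocab,
       life_form_vocab = config$life_form_vocab)

    meta <- sample_meta(data.frame(
      sample_id = sample_rows$sample_id,
      habitat = sample_rows$habitat,
      time = sample_rows$time,
      site = paste0("site", sample_rows$site),
      stratum = "none",
      replicate = 1L,
      stringsAsFactors = FALSE
    ))

    truth <- data.frame(
      species_id = species,
      category = category,
      habitats = vapply(affinity, paste, character(1), collapse = "+"),
      affected = affected,
      boosted_habitat = boosted_hab,
      base_abundance = lambda,
      stringsAsFactors = FALSE, row.names = NULL
    )

    structure(list(table = abundance_table(counts), meta = meta,
                   traits = traits, truth = truth, config = config),
              class = "synthetic_dataset")
  })
}

#' Label-free null configuration
#'
#' A generator config whose samples are exchangeable across habitat labels:
#' every species is ubiquitous and all effect multipliers are 1, so any
#' apparent habitat effect is type-I error. Used for PERMANOVA calibration.
#'
#' @param seed integer seed
#' @param n_common pool size (default 40)
#' @param n_times sampling times (default 1)
#' @param ... further arguments to \code{\link{synthetic_config}}
#' @return a \code{synthetic_config}
#' @export
null_config <- function(seed, n_common = 40, n_times = 1, ...) {
  synthetic_config(n_common = n_common, n_endemic_per_habitat = 0,
                   n_shifting = 0, effect_size = 1, effect_prop = 0,
                   time_effect = 1, n_times = n_times, seed = seed, ...)
}

#' Type-I error and power of the habitat PERMANOVA on synthetic data
#'
#' Simulates repeated datasets and records the rejection rate of the one-way
#' habitat PERMANOVA (square-root Bray-Curtis) at the given alpha: under the
#' label-free null (type-I error) and under a multiplicative habitat effect
#' (power). Exact binomial confidence intervals accompany each rate.
#'
#' @param n_datasets datasets per condition (>= 100 recommended for stable
#'   rates)
#' @param alpha significance level (default 0.05)
#' @param n_perm permutations per test (default 199 for simulation studies)
#' @param effect_size habitat multiplier for the power condition (default 3)
#' @param effect_prop proportion of affected species (default 0.3)
#' @param seed integer seed
#' @param conditions which conditions to run (default both)
#' @param ... further arguments to \code{\link{null_config}} (pool size etc.)
#' @return data.frame (condition, effect_size, n_datasets, rejections, rate,
#'   ci_lower, ci_upper) with 99% exact binomial intervals
#' @export
null_and_power_suite <- function(n_datasets = 500, alpha = 0.05, n_perm = 199,
                                 effect_size = 3, effect_prop = 0.3, seed = 1,
                                 conditions = c("null", "power"), ...) {
  run_condition <- function(es, ep, cond_seed) {
    rejections <- 0L
    for (i in seq_len(n_datasets)) {
      cfg <- null_config(seed = cond_seed + i, ...)
      cfg$effect_size <- es
      cfg$effect_prop <- ep
      ds <- generate_community(cfg)
      d <- bray_curtis(ds$table, sqrt_transform = TRUE)
      # permutation stream decoupled from the generation stream
      res <- permanova(d, ds$meta, terms = "habitat", interaction = FALSE,
                       n_perm = n_perm, seed = cond_seed + 5 * 10^5 + i)
      if (res$p[1] <= alpha) rejections <- rejections + 1L
    }
    rejections
  }
  rows <- list()
  if ("null" %in% conditions) {
    rej <- run_condition(1, 0, seed)
    ci <- stats::binom.test(rej, n_datasets, conf.level = 0.99)$conf.int
    rows[[length(rows) + 1L]] <- data.frame(
      condition = "null", effect_size = 1, n_datasets = n_datasets,
      rejections = rej, rate = rej / n_datasets,
      ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  }
  if ("power" %in% conditions) {
    rej <- run_condition(effect_size, effect_prop, seed + 10^6)
    ci <- stats::binom.test(rej, n_datasets, conf.level = 0.99)$conf.int
    rows[[length(rows) + 1L]] <- data.frame(
      condition = "power", effect_size = effect_size,
      n_datasets = n_datasets, rejections = rej, rate = rej / n_datasets,
      ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
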