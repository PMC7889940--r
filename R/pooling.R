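# replicate pooling and stratum integration: both are pure summations over
# metadata-defined groups, so the grand total count is conserved and no
# species can appear or vanish (only counts add)

pool_by_key <- function(table, meta, key_cols, id_cols) {
  m <- meta_for(table, meta)
  key <- do.call(paste, c(lapply(m[key_cols], as.character), sep = "\r"))
  groups <- unique(key)
  counts <- rowsum(unclass(table), group = factor(key, levels = groups),
                   reorder = FALSE)
  first <- m[match(groups, key), , drop = FALSE]
  new_ids <- do.call(paste, c(lapply(first[id_cols], as.character), sep = "_"))
  rownames(counts) <- new_ids
  new_meta <- data.frame(sample_id = new_ids, first[, setdiff(names(first), "sample_id")],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(table = abundance_table(counts), meta = new_meta,
       group_sizes = as.vector(table(factor(key, levels = groups))))
}

#' Pool replicate samples into site-level communities
#'
#' Field protocols that cannot cover the standard sample area in one grab or
#' quadrat take several replicates per site; analysis then combines them by
#' summing counts within each (habitat, time, site, stratum) group. Pooling is
#' summation (never averaging), so total abundance is conserved.
#'
#' @param table an \code{abundance_table}
#' @param meta a \code{sample_meta}; the \code{replicate} field identifies
#'   replicates within each group
#' @return list with pooled \code{table} and updated \code{meta} (one row per
#'   pooled group, replicate set to 1; sample ids are
#'   habitat_time_site[_stratum]). Unequal replicate group sizes trigger a
#'   warning, not an error.
#' @export
pool_replicates <- function(table, meta) {
  out <- pool_by_key(table, meta,
                     key_cols = c("habitat", "time", "site", "stratum"),
                     id_cols = c("habitat", "time", "site", "stratum"))
  sizes <- out$group_sizes
  if (length(unique(sizes)) > 1L) {
    warning("replicate groups have unequal sizes (",
            paste(sort(unique(sizes)), collapse = ", "),
            "); pooling sums counts regardless", call. = FALSE)
  }
  out$meta$replicate <- 1L
  # drop the "_none" suffix for unstratified samples to keep ids tidy
  plain <- out$meta$stratum == "none"
  new_ids <- out$meta$sample_id
  new_ids[plain] <- sub("_none$", "", new_ids[plain])
  rn <- rownames(out$table)
  rn[plain] <- sub("_none$", "", rn[plain])
  tbl <- unclass(out$table)
  rownames(tbl) <- rn
  out$meta$sample_id <- new_ids
  list(table = abundance_table(tbl), meta = sample_meta(out$meta))
}

#' Integrate strata into whole-site communities
#'
#' For habitats sampled in separate strata (e.g. the above- and belowground
#' components of an eelgrass bed), counts are summed across strata within each
#' (habitat, time, site) so that each site contributes one spatially
#' representative community. The stratum field becomes "none".
#'
#' @param table an \code{abundance_table} (typically replicate-pooled)
#' @param meta a \code{sample_meta}
#' @return list with integrated \code{table} and updated \code{meta}. A site
#'   missing one of its habitat's expected strata is integrated anyway with a
#'   warning.
#' @export
integrate_strata <- function(table, meta) {
  m <- meta_for(table, meta)
  expected <- tapply(m$stratum, m$habitat, function(s) length(unique(s)))
  site_key <- paste(m$habitat, m$time, m$site, sep = "\r")
  n_strata <- tapply(m$stratum, site_key, function(s) length(unique(s)))
  short <- names(n_strata)[n_strata < expected[sub("\r.*", "", names(n_strata))]]
  if (length(short)) {
    warning("sites missing expected strata: ",
            paste(gsub("\r", "/", short), collapse = ", "), call. = FALSE)
  }
  out <- pool_by_key(table, meta,
                     key_cols = c("habitat", "time", "site"),
                     id_cols = c("habitat", "time", "site"))
  out$meta$stratum <- "none"
  out$meta$replicate <- 1L
  list(table = out$table, meta = sample_meta(out$meta))
}
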