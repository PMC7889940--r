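#' Effective number of species (Hill number of order 2)
#'
#' The number of equally abundant species that would give the community's
#' Simpson diversity: with p_i the relative abundances over positive counts,
#' e = 1 / sum(p_i^2) (inverse Simpson). Equal abundances over n species give
#' exactly n; a single species gives 1. Invariant to rescaling counts.
#'
#' @param counts nonnegative numeric vector with at least one positive entry
#' @return e_real, a value in [1, richness]
#' @export
effective_species_number <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  pos <- counts[counts > 0]
  if (length(pos) == 0L) stop("all-zero abundance vector", call. = FALSE)
  p <- pos / sum(pos)
  1 / sum(p^2)
}

#' Select abundant species by the effective-number cut-off
#'
#' Ranks species by descending abundance and keeps the top
#' \code{ceiling(e_real)} ranks, where e_real is the effective number of
#' species of the community. If several species tie with the species at the
#' cut-off rank, all of them are selected, so the choice never depends on
#' species order. Zero-count species are never selected.
#'
#' @param counts nonnegative numeric vector (one community)
#' @param species_ids character vector parallel to counts
#' @return object of class \code{dominance_selection}: list with
#'   \code{e_real}, \code{e_int} (ceiling cut-off), \code{selected} (species
#'   ids in descending-abundance order, ties broken by id for determinism),
#'   and \code{coverage} (selected / total abundance)
#' @export
select_abundant <- function(counts, species_ids) {
  stopifnot(length(counts) == length(species_ids))
  e_real <- effective_species_number(counts)
  e_int <- as.integer(ceiling(e_real - 1e-12))
  pos <- counts > 0
  cnt <- counts[pos]
  ids <- species_ids[pos]
  ord <- order(-cnt, ids, method = "radix")
  cnt <- cnt[ord]
  ids <- ids[ord]
  cut_rank <- min(e_int, length(cnt))
  threshold <- cnt[cut_rank]
  keep <- cnt >= threshold   # includes every species tied at the cut-off rank
  structure(list(
    e_real = e_real,
    e_int = e_int,
    selected = ids[keep],
    selected_counts = cnt[keep],
    coverage = sum(cnt[keep]) / sum(cnt)
  ), class = "dominance_selection")
}

#' @export
print.dominance_selection <- function(x, ...) {
  cat(sprintf("dominance_selection: e = %.3f (cut-off %d), %d species, coverage %.1f%%\n",
              x$e_real, x$e_int, length(x$selected), 100 * x$coverage))
  invisible(x)
}

#' Abundant-species selection for every community in a table
#'
#' @param table an \code{abundance_table} of site-level (pooled/integrated)
#'   communities
#' @return named list of \code{dominance_selection}, one per sample
#' @export
select_abundant_all <- function(table) {
  sp <- species_ids(table)
  sels <- lapply(sample_ids(table), function(s) {
    select_abundant(unclass(table)[s, ], sp)
  })
  names(sels) <- sample_ids(table)
  sels
}

#' Coverage report for dominance selections
#'
#' Per community: the effective number of species, the integer cut-off, how
#' many species were selected (ties can push this above the cut-off), and the
#' fraction of total abundance the selection covers. When metadata is given,
#' habitat x time coverage summaries (min and mean) are attached as an
#' attribute.
#'
#' @param selections named list of \code{dominance_selection} (names = sample
#'   ids)
#' @param meta optional \code{sample_meta}
#' @return data.frame (sample_id, e_real, e_int, n_selected, coverage); when
#'   meta is given, attribute \code{group_summary} holds per habitat x time
#'   min/mean coverage
#' @export
selection_coverage_report <- function(selections, meta = NULL) {
  out <- data.frame(
    sample_id = names(selections),
    e_real = vapply(selections, `[[`, numeric(1), "e_real"),
    e_int = vapply(selections, `[[`, integer(1), "e_int"),
    n_selected = vapply(selections, function(s) length(s$selected), integer(1)),
    coverage = vapply(selections, `[[`, numeric(1), "coverage"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(meta)) {
    m <- meta[match(out$sample_id, meta$sample_id), ]
    grp <- paste(m$habitat, m$time, sep = "/")
    gs <- do.call(rbind, lapply(split(out$coverage, grp), function(v) {
      data.frame(min_coverage = min(v), mean_coverage = mean(v))
    }))
    gs <- data.frame(group = rownames(gs), gs, row.names = NULL,
                     stringsAsFactors = FALSE)
    attr(out, "group_summary") <- gs
  }
  out
}
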