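#' Aggregate selected abundant species into functional groups
#'
#' Sums the counts of each community's selected abundant species within trait
#' categories (primary feeding type or common life form). Unselected species
#' contribute nothing; trait categories with no selected species are retained
#' as zero rows so that every community shares one group vocabulary.
#'
#' @param table the source \code{abundance_table} (site-level communities)
#' @param selections named list of \code{dominance_selection} from
#'   \code{\link{select_abundant_all}}; names must match the table's samples.
#'   Pass NULL to aggregate all species, not just the abundant ones.
#' @param traits a \code{trait_table}
#' @param field \code{"feeding_type"} or \code{"life_form"}
#' @param missing \code{"error"} (default): a selected species without a trait
#'   row is an error; \code{"unclassified"}: such species are pooled into an
#'   "unclassified" group
#' @return object of class \code{functional_abundance}: samples x groups
#'   matrix with attribute \code{field}
#' @export
aggregate_by_trait <- function(table, selections, traits,
                               field = c("feeding_type", "life_form"),
                               missing = c("error", "unclassified")) {
  field <- match.arg(field)
  missing <- match.arg(missing)
  vocab <- if (field == "feeding_type") attr(traits, "feeding_vocab") else attr(traits, "life_form_vocab")
  groups <- vocab
  if (missing == "unclassified") groups <- c(groups, "unclassified")
  m <- unclass(table)
  out <- matrix(0, nrow = nrow(m), ncol = length(groups),
                dimnames = list(rownames(m), groups))
  trait_of <- setNames(as.character(traits[[field]]), traits$species_id)
  for (s in rownames(m)) {
    sel <- if (is.null(selections)) colnames(m)[m[s, ] > 0] else selections[[s]]$selected
    if (is.null(sel)) stop("no selection for sample ", s, call. = FALSE)
    gr <- trait_of[sel]
    if (anyNA(gr)) {
      if (missing == "error") {
        stop("selected species without trait value: ",
             paste(sel[is.na(gr)], collapse = ", "), call. = FALSE)
      }
      gr[is.na(gr)] <- "unclassified"
    }
    out[s, ] <- tapply(m[s, sel], factor(gr, levels = groups), sum, default = 0)
  }
  structure(out, field = field, class = c("functional_abundance", "matrix", "array"))
}

#' Relative functional composition
#'
#' Converts a functional abundance matrix to proportions that sum to one
#' within each grouping unit: per sample, or per habitat x time cell (counts
#' summed across the cell's sites before normalizing).
#'
#' @param ftable a \code{functional_abundance}
#' @param by \code{"sample"} or \code{"habitat_time"}
#' @param meta required \code{sample_meta} when \code{by = "habitat_time"}
#' @return tidy data.frame (unit, group, abundance, proportion)
#' @export
relative_composition <- function(ftable, by = c("sample", "habitat_time"),
                                 meta = NULL) {
  by <- match.arg(by)
  m <- unclass(ftable)
  if (by == "habitat_time") {
    if (is.null(meta)) stop("meta required for habitat_time grouping", call. = FALSE)
    mm <- meta[match(rownames(m), meta$sample_id), ]
    if (anyNA(mm$sample_id)) stop("metadata missing for some samples", call. = FALSE)
    unit <- paste(mm$habitat, mm$time, sep = "/")
    m <- rowsum(m, group = unit, reorder = TRUE)
  }
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("zero total abundance in unit: ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(
    unit = rep(rownames(m), times = ncol(m)),
    group = rep(colnames(m), each = nrow(m)),
    abundance = as.vector(m),
    proportion = as.vector(m / totals),
    stringsAsFactors = FALSE
  )
}
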