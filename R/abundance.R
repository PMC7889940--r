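#' Construct an abundance table
#'
#' An abundance table is the universal currency of the pipeline: a sample x
#' species matrix of nonnegative integer counts (individuals per standardized
#' sample area). Missing (sample, species) pairs are exactly zero.
#'
#' @param counts numeric matrix with unique sample ids as row names and unique
#'   species ids as column names; entries must be finite nonnegative integers.
#' @return An object of class \code{abundance_table}: the validated integer
#'   matrix with \code{sample_ids} on rows and \code{species_ids} on columns.
#' @export
abundance_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample ids as row names and species ids as column names",
         call. = FALSE)
  }
  if (ncol(counts) == 0L) stop("no species", call. = FALSE)
  if (nrow(counts) == 0L) stop("no samples", call. = FALSE)
  rownames(counts) <- trimws(rownames(counts))
  colnames(counts) <- trimws(colnames(counts))
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate species ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(counts))) stop("counts must be finite", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for sample '%s', species '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count for sample '%s', species '%s' (abundance is individuals)",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "double"
  structure(counts, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d species, total count %s\n",
              nrow(x), ncol(x), format(sum(x))))
  invisible(x)
}

#' Sample ids of an abundance table
#' @param table an \code{abundance_table}
#' @return character vector of sample ids
#' @export
sample_ids <- function(table) rownames(table)

#' Species ids of an abundance table
#' @param table an \code{abundance_table}
#' @return character vector of species ids
#' @export
species_ids <- function(table) colnames(table)

#' Read an abundance table from CSV/TSV
#'
#' Long layout requires columns \code{sample_id}, \code{species_id},
#' \code{count}; every pair not present in the file becomes an explicit zero.
#' Wide layout has samples as rows (first column = sample id) and species as
#' columns. Delimiter is inferred from the extension (.csv comma, otherwise
#' tab); a header row is required and ids are whitespace-trimmed.
#'
#' @param path file path
#' @param layout \code{"long"} or \code{"wide"}
#' @return an \code{abundance_table}
#' @export
read_abundance <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  df <- read_delim_table(path)
  if (layout == "long") {
    need <- c("sample_id", "species_id", "count")
    if (!all(need %in% names(df))) {
      stop("long layout requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df$sample_id <- trimws(as.character(df$sample_id))
    df$species_id <- trimws(as.character(df$species_id))
    if (nrow(df) == 0L || !any(nzchar(df$species_id))) {
      stop("no species", call. = FALSE)
    }
    key <- paste(df$sample_id, df$species_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicate (sample, species) pair: ('%s', '%s')",
                   d$sample_id, d$species_id), call. = FALSE)
    }
    samples <- unique(df$sample_id)
    species <- unique(df$species_id)
    m <- matrix(0, nrow = length(samples), ncol = length(species),
                dimnames = list(samples, species))
    m[cbind(match(df$sample_id, samples), match(df$species_id, species))] <-
      df$count
  } else {
    if (ncol(df) < 2L) stop("no species", call. = FALSE)
    ids <- trimws(as.character(df[[1]]))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
  }
  abundance_table(m)
}

#' Write an abundance table to CSV/TSV
#'
#' Writers are deterministic: species columns (and long rows) are ordered
#' lexicographically by species id; samples keep table order.
#'
#' @param table an \code{abundance_table}
#' @param path output path (.csv comma-delimited, otherwise tab)
#' @param layout \code{"long"} or \code{"wide"}
#' @return the path, invisibly
#' @export
write_abundance <- function(table, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  sp <- sort(species_ids(table), method = "radix")
  m <- table[, sp, drop = FALSE]
  if (layout == "long") {
    df <- data.frame(
      sample_id = rep(rownames(m), times = ncol(m)),
      species_id = rep(colnames(m), each = nrow(m)),
      count = as.vector(m),
      stringsAsFactors = FALSE
    )
    df <- df[order(match(df$sample_id, rownames(m)), df$species_id), ]
  } else {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  write_delim_table(df, path)
  invisible(path)
}

#' Collapse counts to presence/absence
#'
#' Maps every positive count to 1, used for incidence-based (Jaccard)
#' analyses. Idempotent.
#'
#' @param table an \code{abundance_table}
#' @return an \code{abundance_table} of 0/1 values
#' @export
to_incidence <- function(table) {
  m <- unclass(table)
  m[] <- as.numeric(m > 0)
  abundance_table(m)
}

#' Per-sample species richness
#' @param table an \code{abundance_table}
#' @return named integer vector: number of species with positive count
#' @export
sample_richness <- function(table) {
  rowSums(unclass(table) > 0)
}
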