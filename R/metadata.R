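#' Construct a sample metadata table
#'
#' One row per sample with its habitat, sampling time, site, optional stratum
#' (e.g. aboveground/belowground for vegetated habitats; "none" elsewhere)
#' and optional replicate index. The combination (habitat, time, site,
#' stratum, replicate) must be unique.
#'
#' @param df data.frame with columns \code{sample_id}, \code{habitat},
#'   \code{time}, \code{site}; optional \code{stratum} (default "none") and
#'   \code{replicate} (default 1).
#' @return validated data.frame of class \code{sample_meta}
#' @export
sample_meta <- function(df) {
  need <- c("sample_id", "habitat", "time", "site")
  if (!all(need %in% names(df))) {
    stop("sample metadata requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- trimws(as.character(df$sample_id))
  for (col in c("habitat", "time", "site")) df[[col]] <- as.character(df[[col]])
  if (is.null(df$stratum)) df$stratum <- "none"
  df$stratum <- as.character(df$stratum)
  df$stratum[is.na(df$stratum) | df$stratum == ""] <- "none"
  if (is.null(df$replicate)) df$replicate <- 1L
  df$replicate[is.na(df$replicate)] <- 1L
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(df[c("habitat", "time", "site", "stratum", "replicate")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    stop("(habitat, time, site, stratum, replicate) not jointly unique",
         call. = FALSE)
  }
  df <- df[, c("sample_id", "habitat", "time", "site", "stratum", "replicate")]
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from CSV/TSV
#' @param path file path
#' @return a \code{sample_meta} data.frame
#' @export
read_sample_meta <- function(path) {
  sample_meta(read_delim_table(path))
}

#' Construct a species trait table
#'
#' One row per species with its primary feeding type (e.g. Ca carnivore, Dp
#' deposit feeder, FS filter/suspension feeder) and common life form (e.g. BU
#' burrowing, SE sedentary, TM tube/mucus-sheath building). Vocabularies are
#' data loaded with the table, not package constants: pass them explicitly or
#' let them default to the codes observed in the table.
#'
#' @param df data.frame with columns \code{species_id}, \code{feeding_type},
#'   \code{life_form}
#' @param feeding_vocab,life_form_vocab allowed codes; default: the distinct
#'   codes present in \code{df}
#' @return data.frame of class \code{trait_table} with the vocabularies
#'   attached as attributes
#' @export
trait_table <- function(df, feeding_vocab = NULL, life_form_vocab = NULL) {
  need <- c("species_id", "feeding_type", "life_form")
  if (!all(need %in% names(df))) {
    stop("trait table requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$species_id <- trimws(as.character(df$species_id))
  df$feeding_type <- as.character(df$feeding_type)
  df$life_form <- as.character(df$life_form)
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id in trait table: ",
         paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", "),
         call. = FALSE)
  }
  feeding_vocab <- feeding_vocab %||% sort(unique(df$feeding_type))
  life_form_vocab <- life_form_vocab %||% sort(unique(df$life_form))
  bad_f <- setdiff(df$feeding_type, feeding_vocab)
  if (length(bad_f)) {
    stop("feeding_type codes outside vocabulary: ", paste(bad_f, collapse = ", "),
         call. = FALSE)
  }
  bad_l <- setdiff(df$life_form, life_form_vocab)
  if (length(bad_l)) {
    stop("life_form codes outside vocabulary: ", paste(bad_l, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  attr(df, "feeding_vocab") <- feeding_vocab
  attr(df, "life_form_vocab") <- life_form_vocab
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a species trait table from CSV/TSV
#'
#' @param path file path
#' @param vocab_path optional path to a JSON file with fields
#'   \code{feeding_type} and \code{life_form} listing the allowed codes; when
#'   omitted, vocabularies are taken from the table itself.
#' @return a \code{trait_table}
#' @export
read_traits <- function(path, vocab_path = NULL) {
  df <- read_delim_table(path)
  fv <- lv <- NULL
  if (!is.null(vocab_path)) {
    v <- jsonlite::read_json(vocab_path, simplifyVector = TRUE)
    fv <- v$feeding_type
    lv <- v$life_form
  }
  trait_table(df, feeding_vocab = fv, life_form_vocab = lv)
}

#' Validate an abundance table against its metadata (and optional traits)
#'
#' Checks that the metadata join is complete in both directions: every sample
#' in the table has exactly one metadata row and vice versa; when traits are
#' supplied, every species has a trait row.
#'
#' @param table an \code{abundance_table}
#' @param meta a \code{sample_meta}
#' @param traits optional \code{trait_table}
#' @return TRUE invisibly, or an error describing the first violation
#' @export
validate_bundle <- function(table, meta, traits = NULL) {
  missing_meta <- setdiff(sample_ids(table), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(meta$sample_id, sample_ids(table))
  if (length(orphan)) {
    stop("metadata rows without samples: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(traits)) {
    missing_tr <- setdiff(species_ids(table), traits$species_id)
    if (length(missing_tr)) {
      stop("species without traits: ", paste(missing_tr, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Export a validated data bundle as JSON
#'
#' @param table an \code{abundance_table}
#' @param meta a \code{sample_meta}
#' @param path output .json path
#' @param traits optional \code{trait_table}
#' @return the path, invisibly
#' @export
export_bundle_json <- function(table, meta, path, traits = NULL) {
  validate_bundle(table, meta, traits)
  sp <- sort(species_ids(table), method = "radix")
  bundle <- list(
    sample_ids = sample_ids(table),
    species_ids = sp,
    counts = unname(unclass(table)[, sp, drop = FALSE]),
    metadata = as.data.frame(meta)
  )
  if (!is.null(traits)) {
    bundle$traits <- as.data.frame(traits)
    bundle$vocabularies <- list(
      feeding_type = attr(traits, "feeding_vocab"),
      life_form = attr(traits, "life_form_vocab")
    )
  }
  jsonlite::write_json(bundle, path, digits = NA, pretty = TRUE)
  invisible(path)
}

# aligned metadata rows for the table's samples, in table order
meta_for <- function(table, meta) {
  validate_bundle(table, meta)
  meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
}
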