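# internal helpers shared across modules

# round half away from zero (R's round() is banker's rounding); survey tables
# report percentages rounded half-up to one decimal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a local RNG state so generators are deterministic without
# clobbering the caller's random stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# delimiter inferred from file extension: .csv -> comma, anything else -> tab
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = infer_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", comment.char = "", fileEncoding = "UTF-8")
}

write_delim_table <- function(df, path) {
  utils::write.table(df, path, sep = infer_sep(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
}
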