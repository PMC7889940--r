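new_dissimilarity <- function(d, method) {
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0), all(is.finite(d)))
  structure(d, method = method, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix (%s): %d samples\n", attr(x, "method"), nrow(x)))
  print(unclass(round(x, 4)))
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i) over (optionally square-root
#' transformed) abundances. The square-root transform (default on) damps the
#' influence of very abundant species before comparing communities. Bounded in
#' [0, 1]; 0 for identical samples, 1 for samples with no species in common.
#' A semimetric: the triangle inequality is not guaranteed.
#'
#' @param table an \code{abundance_table} with >= 2 samples and no all-zero
#'   sample
#' @param sqrt_transform apply sqrt to counts first (default TRUE)
#' @return a \code{dissimilarity_matrix}
#' @export
bray_curtis <- function(table, sqrt_transform = TRUE) {
  m <- unclass(table)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "),
         call. = FALSE)
  }
  if (sqrt_transform) m <- sqrt(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      num <- sum(abs(xi - m[j, ]))
      den <- sum(xi + m[j, ])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  new_dissimilarity(d, if (sqrt_transform) "bray-curtis (sqrt)" else "bray-curtis")
}

#' Binary Jaccard dissimilarity matrix
#'
#' d = 1 - shared/union over presence/absence rows; the pairwise complement of
#' the Jaccard similarity used in the sharing analysis.
#'
#' @param incidence an \code{abundance_table} of 0/1 values (use
#'   \code{\link{to_incidence}}); no all-zero sample allowed
#' @return a \code{dissimilarity_matrix}
#' @export
jaccard_dissim <- function(incidence) {
  m <- unclass(incidence)
  if (!all(m %in% c(0, 1))) stop("incidence table must be binary", call. = FALSE)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "),
         call. = FALSE)
  }
  shared <- m %*% t(m)
  rich <- rowSums(m)
  un <- outer(rich, rich, `+`) - shared
  d <- 1 - shared / un
  diag(d) <- 0
  new_dissimilarity(d, "jaccard (binary)")
}

#' Write a dissimilarity matrix as square CSV with sample-id headers
#' @param d a \code{dissimilarity_matrix}
#' @param path output path
#' @return the path, invisibly
#' @export
write_dissimilarity <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  write_delim_table(df, path)
  invisible(path)
}
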