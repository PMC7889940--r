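# Permutational multivariate ANOVA on a dissimilarity matrix.
#
# Following McArdle & Anderson's direct partitioning: the squared
# dissimilarities are Gower-centered into an inner-product matrix G, and the
# sum of squares attributable to a model term is the trace of the projection
# of G onto the term's column space, taken sequentially (Type I) in the order
# the terms are listed. The pseudo-F is MS(term)/MS(residual); its null
# distribution is obtained by unrestricted permutation of sample labels
# (rows and columns of G permuted together).

gower_center <- function(dm) {
  a <- -0.5 * dm^2
  n <- nrow(a)
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

# sequential projection traces for a list of cumulative hat matrices
term_ss <- function(hats, g) {
  cum <- vapply(hats, function(h) sum(h * g), numeric(1))
  diff(c(0, cum))
}

#' Two-way (or one-way) PERMANOVA with sequential sums of squares
#'
#' Partitions the variation of a dissimilarity matrix among crossed factors
#' (and optionally their interaction) listed in order, using sequential
#' (Type I) sums of squares on the Gower-centered inner-product matrix.
#' P-values come from unrestricted permutation of sample labels, with the
#' (1 + count)/(1 + n_perm) convention so p is never zero.
#'
#' @param d a \code{dissimilarity_matrix} (or symmetric matrix with sample-id
#'   dimnames)
#' @param meta a \code{sample_meta} (or data.frame keyed by sample_id)
#'   covering the samples of \code{d}
#' @param terms character vector of metadata columns, in the order variation
#'   is attributed (e.g. \code{c("habitat", "time")})
#' @param interaction include the interaction of the listed factors after the
#'   main effects (default TRUE when two or more terms)
#' @param n_perm number of permutations (default 9999)
#' @param seed integer seed for the permutations
#' @return object of class \code{permanova_result}: data.frame with rows for
#'   each term, Residuals and Total, columns (term, df, SS, MS, F, R2, p),
#'   plus attributes \code{n_perm} and \code{seed}
#' @export
permanova <- function(d, meta, terms, interaction = length(terms) >= 2,
                      n_perm = 9999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  dm <- as.matrix(d)
  n <- nrow(dm)
  ids <- rownames(dm)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id)) stop("metadata missing for some samples", call. = FALSE)
  for (tm in terms) {
    if (!tm %in% names(m)) stop("unknown factor: ", tm, call. = FALSE)
    if (length(unique(m[[tm]])) < 2L) {
      stop("factor with a single level: ", tm, call. = FALSE)
    }
  }
  fac <- lapply(m[terms], factor)
  term_labels <- terms
  rhs <- paste(terms, collapse = " + ")
  if (interaction) {
    rhs <- paste(rhs, paste(terms, collapse = ":"), sep = " + ")
    term_labels <- c(terms, paste(terms, collapse = " x "))
  }
  mf <- as.data.frame(fac)
  full <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = mf)
  asgn <- attr(full, "assign")
  if (n <= ncol(full)) {
    stop("not enough samples for the model (n must exceed total model df)",
         call. = FALSE)
  }
  # cumulative hat matrices: intercept, then each term added in order;
  # df from rank increments so unbalanced designs are handled correctly
  ranks <- integer(length(term_labels))
  hats <- vector("list", length(term_labels))
  for (k in seq_along(term_labels)) {
    x <- full[, asgn <= k, drop = FALSE]
    q <- qr(x)
    ranks[k] <- q$rank
    hats[[k]] <- tcrossprod(qr.Q(q)[, seq_len(q$rank), drop = FALSE])
  }
  df_terms <- diff(c(1L, ranks))
  if (any(df_terms == 0)) {
    stop("aliased model term (zero df): ",
         paste(term_labels[df_terms == 0], collapse = ", "), call. = FALSE)
  }
  df_res <- n - 1L - sum(df_terms)

  g <- gower_center(dm)
  ss_total <- sum(diag(g))
  ss_terms <- term_ss(hats, g) - c(sum(g) / n, rep(0, length(hats) - 1))
  # the intercept contributes nothing after Gower centering (sum(g) = 0),
  # but subtract it explicitly for numerical hygiene
  ss_res <- ss_total - sum(ss_terms)
  ms_terms <- ss_terms / df_terms
  ms_res <- ss_res / df_res
  f_obs <- ms_terms / ms_res

  exceed <- rep(0L, length(term_labels))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(n)
      gp <- g[idx, idx]
      ss_p <- term_ss(hats, gp)
      ss_res_p <- sum(diag(gp)) - sum(ss_p)
      f_p <- (ss_p / df_terms) / (ss_res_p / df_res)
      exceed <- exceed + (f_p >= f_obs - 1e-12)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(term_labels, "Residuals", "Total"),
    df = c(df_terms, df_res, n - 1L),
    SS = c(ss_terms, ss_res, ss_total),
    MS = c(ms_terms, ms_res, NA),
    F = c(f_obs, NA, NA),
    R2 = c(ss_terms / ss_total, ss_res / ss_total, 1),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", "data.frame")
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations, seed %s)\n",
              attr(x, "n_perm"), attr(x, "seed")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "df"
  df[num] <- lapply(df[num], round, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Default pairwise contrast family over habitat x time cells
#'
#' All habitat pairs within each sampling time, plus each habitat compared
#' between times — the post-hoc family used for community-structure tables.
#'
#' @param meta a \code{sample_meta}
#' @return list of character 2-vectors of "habitat/time" cell labels
#' @export
default_contrast_family <- function(meta) {
  habs <- sort(unique(meta$habitat))
  times <- sort(unique(meta$time))
  fam <- list()
  for (tm in times) {
    cp <- utils::combn(habs, 2)
    for (i in seq_len(ncol(cp))) {
      fam[[length(fam) + 1L]] <- paste(cp[, i], tm, sep = "/")
    }
  }
  if (length(times) >= 2) {
    tp <- utils::combn(times, 2)
    for (h in habs) {
      for (i in seq_len(ncol(tp))) {
        fam[[length(fam) + 1L]] <- paste(h, tp[, i], sep = "/")
      }
    }
  }
  fam
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' One-way PERMANOVA on the subset of samples of each contrast (a pair of
#' habitat x time cells), with raw p-values corrected across the whole
#' contrast family by the false discovery rate method.
#'
#' @param d a \code{dissimilarity_matrix}
#' @param meta a \code{sample_meta}
#' @param contrasts list of character 2-vectors of "habitat/time" cell
#'   labels; default \code{\link{default_contrast_family}(meta)}
#' @param n_perm permutations per contrast (default 9999)
#' @param seed integer seed; contrast c uses seed + c so contrasts are
#'   independent but the family is reproducible
#' @return data.frame (group_a, group_b, n_a, n_b, F, p_raw, p_adj)
#' @export
pairwise_permanova <- function(d, meta, contrasts = NULL, n_perm = 9999,
                               seed = 1) {
  dm <- as.matrix(d)
  m <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
  cell <- paste(m$habitat, m$time, sep = "/")
  contrasts <- contrasts %||% default_contrast_family(meta)
  rows <- vector("list", length(contrasts))
  for (ci in seq_along(contrasts)) {
    ab <- contrasts[[ci]]
    sel <- cell %in% ab
    if (sum(cell == ab[1]) < 2L || sum(cell == ab[2]) < 2L) {
      stop("contrast with fewer than 2 samples per group: ",
           paste(ab, collapse = " vs "), call. = FALSE)
    }
    sub_ids <- rownames(dm)[sel]
    sub_meta <- data.frame(sample_id = sub_ids, group = cell[sel],
                           stringsAsFactors = FALSE)
    res <- permanova(dm[sel, sel], sub_meta, terms = "group",
                     interaction = FALSE, n_perm = n_perm, seed = seed + ci)
    rows[[ci]] <- data.frame(
      group_a = ab[1], group_b = ab[2],
      n_a = sum(cell == ab[1]), n_b = sum(cell == ab[2]),
      F = res$F[1], p_raw = res$p[1], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_bh(out$p_raw)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: p_(i) * m / i for the ordered p-values, with
#' monotonicity enforced by a cumulative minimum from the largest rank, capped
#' at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1]
#' @return adjusted p-values in the original order
#' @export
fdr_bh <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  ord <- order(pvals, method = "radix")
  adj <- pvals[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  adj[order(ord)]
}
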