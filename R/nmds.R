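# Non-metric multidimensional scaling by stress majorization.
#
# The configuration is updated with the Guttman transform toward disparities
# obtained by monotone (isotonic) least-squares regression of configuration
# distances on the rank order of the input dissimilarities. Ties in the
# dissimilarities use the primary ("weak") treatment: tied pairs are free to
# take different disparities. Badness of fit is Kruskal's stress-1,
# sqrt(sum((d - dhat)^2) / sum(d^2)), which depends on the dissimilarities
# only through their ranks and is invariant to uniform rescaling of the
# configuration.

# pool-adjacent-violators: least-squares nondecreasing fit
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y
  wt <- w
  sz <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]
    wt[m] <- w[i]
    sz[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) / tw
      wt[m - 1L] <- tw
      sz[m - 1L] <- sz[m - 1L] + sz[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = sz[seq_len(m)])
}

config_distances <- function(x) as.vector(stats::dist(x))

kruskal_stress <- function(d, dhat) sqrt(sum((d - dhat)^2) / sum(d^2))

nmds_one_start <- function(delta_order, x0, max_iter, tol) {
  n <- nrow(x0)
  x <- scale(x0, center = TRUE, scale = FALSE)
  d <- config_distances(x)
  # primary tie treatment: within tied dissimilarity blocks, order by current
  # distance so the monotone fit leaves ties unconstrained
  stress_trace <- numeric(0)
  prev_stress <- Inf
  # lower-triangle pair indices in stats::dist storage order (column-major)
  pairs <- which(lower.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  for (iter in seq_len(max_iter)) {
    ord <- order(delta_order$block, d, method = "radix")
    dhat <- numeric(length(d))
    dhat[ord] <- pava(d[ord])
    stress <- kruskal_stress(d, dhat)
    if (stress > prev_stress + 1e-12) {
      x <- x_prev
      stress <- prev_stress
      break
    }
    stress_trace <- c(stress_trace, stress)
    if (prev_stress - stress < tol) break
    prev_stress <- stress
    x_prev <- x
    if (stress == 0) break
    # Guttman transform with unit weights: x <- B(x) x / n
    ratio <- ifelse(d > 0, dhat / d, 0)
    b <- matrix(0, n, n)
    b[pairs] <- -ratio
    b <- b + t(b)
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n
    x <- scale(x, center = TRUE, scale = FALSE)
    d <- config_distances(x)
  }
  list(points = x, stress = stress, trace = stress_trace, iters = iter)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Ordains samples in k dimensions so that configuration distances preserve
#' the rank order of the input dissimilarities, minimizing Kruskal's stress-1
#' by iterative majorization with monotone regression. The first start is the
#' classical (metric) MDS solution; the remaining starts are random. The best
#' start is returned. Ordinations with stress below 0.2 are flagged as
#' accepted, the conventional threshold for trustworthy 2-D configurations.
#'
#' @param d a \code{dissimilarity_matrix} (or symmetric matrix) with
#'   n >= k + 2 samples
#' @param k number of dimensions (default 2)
#' @param n_restarts number of starts including the metric-MDS start
#'   (default 20)
#' @param max_iter majorization iterations per start (default 300)
#' @param tol stress-improvement convergence tolerance (default 1e-6)
#' @param seed integer seed for the random starts (required for
#'   reproducibility)
#' @return object of class \code{nmds_result}: list with \code{points}
#'   (centered n x k coordinates), \code{stress}, \code{converged},
#'   \code{accepted} (stress < 0.2), \code{n_restarts}, \code{best_restart},
#'   and \code{stress_trace} of the best start
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-6,
                 seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < k + 2) stop("need at least k + 2 samples", call. = FALSE)
  delta <- as.vector(stats::as.dist(dm))
  if (length(unique(delta)) < 2L) {
    stop("no rank structure: all dissimilarities equal", call. = FALSE)
  }
  # rank blocks of the dissimilarities (ties share a block id)
  ord0 <- order(delta, method = "radix")
  block <- match(delta, sort(unique(delta)))
  delta_order <- list(order = ord0, block = block)

  fits <- with_seed(seed, {
    starts <- vector("list", n_restarts)
    x_metric <- tryCatch(
      stats::cmdscale(dm, k = k),
      error = function(e) NULL
    )
    if (!is.null(x_metric) && ncol(x_metric) == k) {
      starts[[1]] <- x_metric
    } else {
      starts[[1]] <- matrix(stats::rnorm(n * k), n, k)
    }
    for (r in seq_len(n_restarts)[-1]) {
      starts[[r]] <- matrix(stats::rnorm(n * k), n, k)
    }
    lapply(starts, nmds_one_start, delta_order = delta_order,
           max_iter = max_iter, tol = tol)
  })
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  best <- which.min(stresses)
  fit <- fits[[best]]
  pts <- fit$points
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(
    points = pts,
    stress = fit$stress,
    all_stresses = stresses,
    converged = fit$iters < max_iter,
    accepted = fit$stress < 0.2,
    n_restarts = n_restarts,
    best_restart = best,
    stress_trace = fit$trace,
    seed = seed
  ), class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dims, stress-1 = %.4f (%s; best of %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$accepted) "accepted, < 0.2" else "NOT accepted, >= 0.2",
              x$n_restarts))
  invisible(x)
}
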