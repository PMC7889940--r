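test_that("Bray-Curtis matches hand values, bounds, and a brute-force oracle", {
  tab <- abundance_table(rbind(s1 = c(a = 1, b = 3), s2 = c(a = 3, b = 1),
                               s3 = c(a = 1, b = 3)))
  d <- bray_curtis(tab, sqrt_transform = TRUE)
  expect_equal(d["s1", "s2"], (sqrt(3) - 1) / (sqrt(3) + 1), tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)

  disj <- abundance_table(rbind(s1 = c(a = 4, b = 2, c = 0, d = 0),
                                s2 = c(a = 0, b = 0, c = 1, d = 9)))
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)

  zero <- rbind(s1 = c(a = 1), s2 = c(a = 0))
  expect_error(bray_curtis(abundance_table(zero)), "all-zero sample.*s2")

  # naive double-loop oracle on random fixtures, with and without transform
  set.seed(12)
  m <- matrix(rpois(8 * 10, 3), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("sp", 1:10)))
  m[, 1] <- m[, 1] + 1
  for (tr in c(TRUE, FALSE)) {
    d2 <- bray_curtis(abundance_table(m), sqrt_transform = tr)
    x <- if (tr) sqrt(m) else m
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(d2[i, j], sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]))
    }
    expect_true(isSymmetric(unname(unclass(d2))))
    expect_true(all(diag(d2) == 0))
  }
})

test_that("binary Jaccard dissimilarity agrees with the sharing-index complement", {
  inc <- abundance_table(rbind(s1 = c(a = 1, b = 1, c = 0),
                               s2 = c(a = 0, b = 1, c = 1)))
  d <- jaccard_dissim(inc)
  expect_equal(d["s1", "s2"], 2 / 3)
  expect_error(jaccard_dissim(toy_table()), "binary")

  set.seed(3)
  m <- matrix(rbinom(6 * 12, 1, 0.5), 6, 12,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:12)))
  m[, 1] <- 1
  dj <- jaccard_dissim(abundance_table(m))
  for (i in 1:5) for (j in (i + 1):6) {
    a <- colnames(m)[m[i, ] > 0]
    b <- colnames(m)[m[j, ] > 0]
    expect_equal(dj[i, j], 1 - jaccard_index(a, b))
  }
  expect_true(all((unclass(dj) == 0) == (as.matrix(dist(m, "binary")) == 0)))
})

test_that("NMDS recovers planar configurations with near-zero stress", {
  set.seed(42)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  dm <- as.matrix(dist(pts))
  dimnames(dm) <- list(paste0("p", 1:10), paste0("p", 1:10))
  fit <- nmds(dm, k = 2, n_restarts = 5, seed = 7)
  expect_lt(fit$stress, 0.01)
  expect_true(fit$accepted)
  # coordinates centered at the origin
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
  # best-of-restarts is the minimum
  expect_equal(fit$stress, min(fit$all_stresses))
  # stress non-increasing across iterations within the winning restart
  expect_true(all(diff(fit$stress_trace) <= 1e-12))
})

test_that("NMDS stress depends on dissimilarities only through their ranks", {
  set.seed(5)
  m <- matrix(rpois(9 * 8, 4) + 1, 9, 8,
              dimnames = list(paste0("s", 1:9), paste0("sp", 1:8)))
  d1 <- bray_curtis(abundance_table(m))
  d2 <- unclass(d1) * 2
  f1 <- nmds(d1, seed = 11, n_restarts = 5)
  f2 <- nmds(d2, seed = 11, n_restarts = 5)
  expect_equal(f1$stress, f2$stress, tolerance = 1e-10)

  flat <- matrix(0.5, 4, 4); diag(flat) <- 0
  dimnames(flat) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_error(nmds(flat, seed = 1), "no rank structure")
  expect_error(nmds(unclass(d1)[1:3, 1:3], k = 2, seed = 1), "k \\+ 2")
})

test_that("NMDS stress is close to vegan's monoMDS solution", {
  skip_if_not_installed("vegan")
  set.seed(8)
  m <- matrix(rpois(12 * 10, 5) + 1, 12, 10,
              dimnames = list(paste0("s", 1:12), paste0("sp", 1:10)))
  d <- bray_curtis(abundance_table(m))
  ours <- nmds(d, seed = 2, n_restarts = 20)
  ref <- vegan::metaMDS(stats::as.dist(unclass(d)), k = 2, trace = 0)
  expect_equal(ours$stress, ref$stress, tolerance = 0.02)
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F on univariate data", {
  set.seed(15)
  y <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  dm <- as.matrix(dist(y))
  dimnames(dm) <- list(paste0("u", 1:18), paste0("u", 1:18))
  md <- data.frame(sample_id = paste0("u", 1:18), habitat = g,
                   time = "T1", site = seq_len(18))
  res <- permanova(dm, md, "habitat", interaction = FALSE, n_perm = 9, seed = 1)
  f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$F[1], f_aov, tolerance = 1e-12)
  # and the SS decomposition matches the classical one
  expect_equal(res$SS[1], summary(stats::aov(y ~ g))[[1]]$`Sum Sq`[1],
               tolerance = 1e-10)
})

test_that("two-way PERMANOVA matches vegan::adonis2 with sequential SS", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- matrix(rpois(20 * 15, 6), 20, 15,
              dimnames = list(paste0("s", 1:20), paste0("sp", 1:15)))
  m[, 1] <- m[, 1] + 1
  d <- bray_curtis(abundance_table(m))
  md <- data.frame(sample_id = rownames(m),
                   habitat = rep(c("A", "B", "C", "D"), each = 5),
                   time = rep(c("T1", "T2"), 10), site = 1:20)
  ours <- permanova(d, md, c("habitat", "time"), n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ habitat * time,
                        data = md, permutations = 99, by = "terms")
  expect_equal(ours$SS[1:4], ref$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(ours$F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(ours$R2[1:4], ref$R2[1:4], tolerance = 1e-10)
  # R2 of all non-total rows sums to one; df sum to n - 1
  expect_equal(sum(ours$R2[ours$term != "Total"]), 1)
  expect_equal(sum(ours$df[ours$term %in% c("habitat", "time", "habitat x time",
                                            "Residuals")]), 19)
})

test_that("PERMANOVA p-values are deterministic given a seed and bounded below", {
  set.seed(20)
  # two clearly separated clusters of 10: with choose(20, 10) distinct label
  # splits, a random permutation virtually never reproduces the separation,
  # so p reaches its attainable minimum (1 + 0) / (1 + n_perm)
  m <- rbind(matrix(rpois(10 * 8, 2), 10, 8),
             matrix(rpois(10 * 8, 2) + 60, 10, 8))
  dimnames(m) <- list(paste0("s", 1:20), paste0("sp", 1:8))
  md <- data.frame(sample_id = rownames(m), habitat = rep(c("lo", "hi"), each = 10),
                   time = "T1", site = 1:20)
  d <- bray_curtis(abundance_table(m))
  res <- permanova(d, md, "habitat", interaction = FALSE, n_perm = 999, seed = 4)
  expect_equal(res$p[1], 0.001)
  res2 <- permanova(d, md, "habitat", interaction = FALSE, n_perm = 999, seed = 4)
  expect_identical(res$p, res2$p)
  expect_error(permanova(d, md, "time", interaction = FALSE, n_perm = 99),
               "single level")
  expect_error(permanova(d, md, "habitat", n_perm = 0), "n_perm")
})

test_that("pairwise PERMANOVA corrects across the whole contrast family", {
  set.seed(9)
  meta <- toy_meta(n_habitats = 3, sites = 4, times = c("T1", "T2"))
  tab <- random_table(meta, n_species = 10, lambda = 5, seed = 14)
  d <- bray_curtis(tab)
  fam <- default_contrast_family(meta)
  # 3 habitat pairs x 2 times + 3 habitats between times = 9 contrasts
  expect_length(fam, 9L)
  pw <- pairwise_permanova(d, meta, n_perm = 49, seed = 2)
  expect_equal(nrow(pw), 9L)
  expect_equal(pw$p_adj, fdr_bh(pw$p_raw))
  expect_true(all(pw$p_adj >= pw$p_raw))
  # single contrast: adjusted equals raw
  one <- pairwise_permanova(d, meta, contrasts = fam[1], n_perm = 49, seed = 2)
  expect_equal(one$p_adj, one$p_raw)
  expect_error(pairwise_permanova(d, meta,
                                  contrasts = list(c("H1/T1", "H9/T9")),
                                  n_perm = 9),
               "fewer than 2 samples")
})

test_that("BH-FDR matches hand values and the brute-force step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  # definition: adj_(i) = min(1, min_{j >= i} m * p_(j) / j)
  brute_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    adj <- vapply(seq_len(m), function(i) min(1, m * ps[i:m] / (i:m)),
                  numeric(1))
    out <- numeric(m)
    out[ord] <- adj
    out
  }
  set.seed(6)
  for (rep in 1:10) {
    p <- runif(sample(3:25, 1))
    got <- fdr_bh(p)
    expect_equal(got, brute_bh(p), tolerance = 1e-12)
    # monotone in raw p order, never below raw
    expect_true(all(got >= p - 1e-15))
    expect_true(all(diff(got[order(p)]) >= -1e-15))
  }
})
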