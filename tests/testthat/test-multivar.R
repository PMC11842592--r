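test_that("distance_matrix implements its metrics", {
  pts <- rbind(c(0, 0), c(1, 2))
  expect_equal(distance_matrix(pts, "manhattan")$d[1, 2], 3)
  expect_equal(distance_matrix(pts, "euclidean")$d[1, 2], sqrt(5))
  same <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_true(all(distance_matrix(same)$d == 0))
  expect_error(distance_matrix(rbind(c(NA, 1), c(0, 0))), "missing")
  # triangle inequality on random fixtures
  set.seed(3)
  for (m in c("manhattan", "euclidean")) {
    d <- distance_matrix(matrix(rnorm(20), 10, 2), m)$d
    for (i in 1:10) for (j in 1:10) for (k in 1:10) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("pseudo-F agrees with a naive two-group partition oracle and vegan", {
  set.seed(10)
  x <- rbind(matrix(rnorm(16, 0), 8, 2), matrix(rnorm(12, 2), 6, 2))
  g <- rep(c("a", "b"), c(8, 6))
  d <- distance_matrix(x, "manhattan")
  res <- permanova(d, g, n_perm = 99, seed = 1, exact = FALSE)

  # naive oracle: explicit sums over within-group pairs
  n <- 14; d2 <- d$d^2
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- sum(d2[1:8, 1:8][upper.tri(d2[1:8, 1:8])]) / 8 +
    sum(d2[9:14, 9:14][upper.tri(d2[9:14, 9:14])]) / 6
  f_oracle <- ((sst - ssw) / 1) / (ssw / 12)
  expect_equal(res$table$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$table$R2, (sst - ssw) / sst, tolerance = 1e-10)

  skip_if_not_installed("vegan")
  va <- vegan::adonis2(stats::dist(x, method = "manhattan") ~ g, permutations = 99)
  expect_equal(res$table$F, va$F[1], tolerance = 1e-10)
  expect_equal(res$table$R2, va$R2[1], tolerance = 1e-10)
})

test_that("small-n permutation p matches exhaustive enumeration", {
  set.seed(4)
  x <- matrix(rnorm(14), 7, 2)
  g <- c("a", "a", "a", "b", "b", "b", "b")
  d <- distance_matrix(x, "euclidean")
  res <- permanova(d, g, n_perm = 9999, seed = 1)   # exact path for n <= 7
  expect_equal(res$method, "exact")

  # independent enumeration oracle over all C(7,3) relabelings
  d2 <- d$d^2
  f_of <- function(lab) {
    sst <- sum(d2) / (2 * 7)
    ssw <- 0
    for (l in unique(lab)) {
      i <- which(lab == l)
      ssw <- ssw + sum(d2[i, i]) / (2 * length(i))
    }
    ((sst - ssw) / 1) / (ssw / 5)
  }
  obs <- f_of(g)
  combos <- utils::combn(7, 3, simplify = FALSE)
  fs <- vapply(combos, function(ii) {
    lab <- rep("b", 7); lab[ii] <- "a"; f_of(lab)
  }, numeric(1))
  expect_equal(res$table$p, mean(fs >= obs - 1e-12))
})

test_that("perfectly separated clusters reach the minimum attainable p", {
  set.seed(5)
  x <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2), matrix(rnorm(20, 50, 0.05), 10, 2))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(distance_matrix(x), g, n_perm = 99, seed = 2, exact = FALSE)
  expect_equal(res$table$p, 1 / 100)
  expect_error(permanova(distance_matrix(x), rep("a", 20), 99), "design error")
})

test_that("seeded runs are bit-reproducible", {
  set.seed(6)
  x <- matrix(rnorm(40), 20, 2)
  g <- rep(c("a", "b"), each = 10)
  d <- distance_matrix(x)
  r1 <- permanova(d, g, n_perm = 199, seed = 42, exact = FALSE)
  r2 <- permanova(d, g, n_perm = 199, seed = 42, exact = FALSE)
  expect_identical(r1$table$p, r2$table$p)
})

test_that("marginal-SS multi-factor PERMANOVA partitions like adonis2 by margin", {
  skip_if_not_installed("vegan")
  set.seed(7)
  f1 <- rep(c("x", "y"), each = 12)
  f2 <- rep(c("u", "v", "w"), times = 8)
  x <- matrix(rnorm(48), 24, 2) + 0.8 * (f1 == "x")
  d <- distance_matrix(x, "manhattan")
  res <- permanova(d, data.frame(a = f1, b = f2), n_perm = 199, seed = 1)
  va <- vegan::adonis2(stats::dist(x, method = "manhattan") ~ a + b,
                       data = data.frame(a = f1, b = f2),
                       permutations = 199, by = "margin")
  expect_equal(res$table$ss, va$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(res$table$F, va$F[1:2], tolerance = 1e-10)
})

test_that("Benjamini-Yekutieli adjustment matches the hand formula and base R", {
  # m = 3, c(3) = 11/6: all three step up to 0.01 * 3 * (11/6) = 0.055
  expect_equal(adjust_by(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  expect_equal(adjust_by(0.2), 0.2)  # single comparison: unchanged
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(adjust_by(p), stats::p.adjust(p, method = "BY"))
    expect_true(all(adjust_by(p) >= p - 1e-15))
  }
})

test_that("pairwise_permanova tests all pairs and adjusts", {
  set.seed(9)
  x <- rbind(matrix(rnorm(12, 0, 0.1), 6, 2),
             matrix(rnorm(12, 5, 0.1), 6, 2),
             matrix(rnorm(12, 10, 0.1), 6, 2))
  g <- rep(c("a", "b", "c"), each = 6)
  pw <- pairwise_permanova(distance_matrix(x), g, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adj >= pw$p))
  expect_true(all(pw$p == 0.01))
})

test_that("dispersion outlier screen flags only genuine outliers", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2), c(10, 10))
  g <- rep("a", 16)
  ids <- sprintf("s%02d", 1:16)
  expect_equal(dispersion_outliers(pts, g, k = 1.5, labels = ids), "s16")
  # identical points -> nothing flagged
  expect_length(dispersion_outliers(matrix(1, 5, 2), rep("a", 5)), 0)
  # invariant to sample ordering
  ord <- sample(16)
  expect_equal(dispersion_outliers(pts[ord, ], g, k = 1.5, labels = ids[ord]), "s16")
  expect_warning(dispersion_outliers(matrix(rnorm(4), 2, 2), rep("a", 2)), "skipped")
})

test_that("Mardia test accepts normal data and rejects gross non-normality", {
  set.seed(12)
  x <- matrix(rnorm(400), 200, 2)
  m <- mardia_test(x)
  expect_gt(m$p_skew, 0.01)
  y <- matrix(rexp(400)^3, 200, 2)
  expect_lt(mardia_test(y)$p_skew, 1e-4)
})
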