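test_that("epsilon index has exact anchors and hand-derived values", {
  for (K in 2:10) {
    expect_identical(epsilon_index(rep(1 / K, K)), 0)
    expect_equal(epsilon_index(c(1, rep(0, K - 1))), 1, tolerance = 1e-15)
  }
  # K = 3, p = (0.5, 0.5, 0): ||p-u|| = sqrt(6)/6, Dmax = sqrt(2/3) -> 0.5
  expect_equal(epsilon_index(c(0.5, 0.5, 0)), 0.5, tolerance = 1e-12)
  expect_error(epsilon_index(c(0.7, 0.7)), "simplex")
  expect_error(epsilon_index(1), "K >= 2")
})

test_that("epsilon is permutation-invariant and monotone toward vertices", {
  set.seed(1)
  for (i in 1:20) {
    p <- as.numeric(isodiet:::.rdirichlet(1, rep(1, 4)))
    expect_equal(epsilon_index(p), epsilon_index(sample(p)))
  }
  u <- rep(1 / 4, 4); v <- c(1, 0, 0, 0)
  path <- sapply(seq(0, 1, 0.1), function(t) epsilon_index((1 - t) * u + t * v))
  expect_true(all(diff(path) > 0))
  expect_equal(path[1], 0); expect_equal(path[11], 1)
})

test_that("combine_sources merges proportions additively per draw", {
  mp <- rbind(c(0.3, 0.4, 0.3), c(0.2, 0.5, 0.3))
  colnames(mp) <- c("pelagic_UE", "pelagic_LE_nwGSL", "sand_lance")
  est <- make_estimates(mp)
  id_map <- setNames(colnames(mp), colnames(mp))
  same <- combine_sources(est, id_map)
  expect_equal(same$mean_p, mp)

  merged <- combine_sources(est, c(pelagic_UE = "pelagic", pelagic_LE_nwGSL = "pelagic",
                                   sand_lance = "sand_lance"))
  expect_equal(ncol(merged$mean_p), 2)
  expect_equal(unname(merged$mean_p[1, "pelagic"]), 0.7)
  expect_true(all(abs(rowSums(merged$mean_p) - 1) < 1e-12))
  expect_error(combine_sources(est, c(pelagic_UE = "pelagic")), "misses")

  # consistency: epsilon on merged means equals direct computation on
  # merged draws when draws are degenerate at the means
  eps_merged <- apply(merged$mean_p, 1, epsilon_index)
  direct <- apply(merged$draws[1, , ], 1, epsilon_index)
  expect_equal(eps_merged, direct)
})

test_that("epsilon_population summarizes classes and detects constructed gaps", {
  # all uniform diets -> epsilon 0 everywhere, class difference p ~ 1
  mp <- matrix(1 / 3, 12, 3)
  est <- make_estimates(mp, class = rep(c("adult_male", "adult_female"), each = 6))
  ep <- epsilon_population(est, n_perm = 99, seed = 1)
  expect_true(all(ep$per_consumer$epsilon == 0))
  expect_gt(ep$pairwise$p, 0.9)

  # constructed specialization gap: males specialized, females generalist
  mp2 <- rbind(matrix(rep(c(0.9, 0.05, 0.05), 6), 6, 3, byrow = TRUE),
               matrix(rep(c(0.4, 0.3, 0.3), 6), 6, 3, byrow = TRUE))
  est2 <- make_estimates(mp2, class = rep(c("adult_male", "adult_female"), each = 6))
  ep2 <- epsilon_population(est2, n_perm = 999, seed = 2)
  # the observed gap is attained only by the two extreme relabelings, so the
  # permutation p is near 2 / choose(12, 6)
  expect_lt(ep2$pairwise$p, 0.01)
  # class SD matches brute force
  eps <- apply(mp2, 1, epsilon_index)
  expect_equal(ep2$class_summary$sd[ep2$class_summary$class == "adult_male"],
               sd(eps[1:6]))
})

test_that("heterogeneity measures distance to class centroid", {
  # identical diets within groups -> all distances zero
  mp <- rbind(matrix(rep(c(0.6, 0.2, 0.2), 5), 5, 3, byrow = TRUE),
              matrix(rep(c(0.2, 0.6, 0.2), 5), 5, 3, byrow = TRUE))
  est <- make_estimates(mp, class = rep(c("adult_male", "adult_female"), each = 5))
  # all-zero distances make the dispersion pseudo-F degenerate (warned)
  h <- suppressWarnings(heterogeneity(est, "class", n_perm = 99, seed = 1))
  expect_true(all(h$distances$distance == 0))

  # tight group A vs dispersed group B: B has larger dispersion, test significant
  set.seed(3)
  a <- isodiet:::.rdirichlet(10, c(60, 30, 30))
  b <- isodiet:::.rdirichlet(10, c(2, 1, 1))
  est2 <- make_estimates(rbind(a, b),
                         class = rep(c("adult_male", "adult_female"), each = 10))
  h2 <- heterogeneity(est2, "class", n_perm = 999, seed = 4)
  disp <- h2$dispersion
  expect_gt(disp$mean_distance[disp$group == "adult_female"],
            disp$mean_distance[disp$group == "adult_male"])
  expect_lt(h2$test$table$p, 0.05)

  # distances invariant to source (coordinate) ordering
  perm <- c(3, 1, 2)
  est3 <- make_estimates(rbind(a, b)[, perm],
                         class = rep(c("adult_male", "adult_female"), each = 10))
  h3 <- heterogeneity(est3, "class", n_perm = 9, seed = 1)
  expect_equal(h3$distances$distance, h2$distances$distance)

  # small groups excluded with a warning
  est4 <- make_estimates(mp, class = c(rep("adult_male", 8), "adult_female", "juvenile"))
  expect_warning(heterogeneity(est4, "class", n_perm = 9), "excluding")
})

test_that("diet_difference_test agrees with a direct permanova call", {
  set.seed(5)
  mp <- rbind(isodiet:::.rdirichlet(8, c(8, 2, 2)), isodiet:::.rdirichlet(8, c(2, 8, 2)))
  cls <- rep(c("adult_male", "adult_female"), each = 8)
  est <- make_estimates(mp, class = cls)
  t1 <- diet_difference_test(est, "class", n_perm = 199, seed = 7)
  d <- distance_matrix(mp, "euclidean", labels = est$table$sample_id)
  t2 <- permanova(d, cls, n_perm = 199, seed = 7, exact = FALSE)
  expect_equal(t1$global$table$F, t2$table$F)
  expect_equal(t1$global$table$p, t2$table$p)
  expect_null(t1$pairwise)  # only two levels
  expect_error(diet_difference_test(make_estimates(mp), "class"), "2 factor levels")
})
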