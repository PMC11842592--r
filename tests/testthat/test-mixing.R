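test_that("ILR transform has the documented basis and round-trips", {
  expect_equal(ilr_transform(rep(0.25, 4)), rep(0, 3))
  # K = 2 closed form
  p2 <- c(0.731, 0.269)
  expect_equal(ilr_transform(p2), (1 / sqrt(2)) * log(0.731 / 0.269))
  expect_error(ilr_transform(c(0.5, 0.5, 0)), "zero")
  set.seed(1)
  for (K in 2:6) {
    p <- as.numeric(isodiet:::.rdirichlet(1, rep(1, K)))
    expect_equal(ilr_inverse(ilr_transform(p), K), p, tolerance = 1e-10)
  }
})

test_that("mixture moments follow the concentration-weighted formulas", {
  tdf <- tdf_spec(c(1.3, 2.4), c(0.5, 0.5))
  src <- make_sources(3)
  # single-source limit
  mm <- mixture_moments(c(1, 0, 0), src, tdf)
  expect_equal(mm$mean, c(src$mean_d13c[1] + 1.3, src$mean_d15n[1] + 2.4))
  expect_equal(mm$var, c(src$sd_d13c[1]^2 + 0.25, src$sd_d15n[1]^2 + 0.25))

  # equal p, equal concentrations: mean of shifted source means
  s2 <- make_sources(2)
  mm2 <- mixture_moments(c(0.5, 0.5), s2, tdf)
  expect_equal(mm2$mean[1], mean(s2$mean_d13c) + 1.3)

  # hand-derived concentration weights: p=(0.6,0.4), conc=(0.4,0.2) -> w=(0.75,0.25)
  src_h <- make_sources(2)
  src_h$conc_c <- c(0.4, 0.2)
  mm3 <- mixture_moments(c(0.6, 0.4), src_h, tdf)
  w <- c(0.75, 0.25)
  expect_equal(mm3$mean[1], sum(w * (src_h$mean_d13c + 1.3)))
  expect_equal(mm3$var[1], sum(w^2 * (src_h$sd_d13c^2 + 0.25)))
  expect_error(mixture_moments(c(1, 0), {s <- make_sources(2); s$conc_c <- c(0, 0.4); s},
                               tdf), "concentration")
})

test_that("log-likelihood matches closed forms and a brute-force oracle", {
  src <- make_sources(2, sd = sqrt(1 - 0.25))  # combined var with tdf sd 0.5 = 1
  tdf <- tdf_spec(c(0, 0), c(0.5, 0.5))
  p <- c(1, 0)
  mu <- c(src$mean_d13c[1], src$mean_d15n[1])
  expect_equal(mix_loglik(mu, p, src, tdf), 2 * (-0.5 * log(2 * pi)))

  # xi = 1 equals the process-only likelihood; brute-force moment oracle
  set.seed(2)
  for (i in 1:10) {
    pp <- as.numeric(isodiet:::.rdirichlet(1, c(1, 1)))
    y <- c(rnorm(1, -19, 2), rnorm(1, 14, 2))
    ll <- mix_loglik(y, pp, src, tdf, error_mult = c(1, 1))
    # oracle: sums written out longhand
    mo <- sapply(1:2, function(j) {
      cc <- c(src$conc_c[1:2], src$conc_n[1:2])[(j - 1) * 2 + 1:2]
      w <- pp * cc / sum(pp * cc)
      mu <- sum(w * (c(src$mean_d13c, src$mean_d15n)[(j - 1) * 2 + 1:2] + tdf$mean[j]))
      v <- sum(w^2 * (c(src$sd_d13c, src$sd_d15n)[(j - 1) * 2 + 1:2]^2 + tdf$sd[j]^2))
      dnorm(y[j], mu, sqrt(v), log = TRUE)
    })
    expect_equal(ll, sum(mo), tolerance = 1e-12)
    xi <- c(2, 3)
    expect_equal(mix_loglik(y, pp, src, tdf, xi),
                 sum(sapply(1:2, function(j) {
                   cc <- c(src$conc_c[1:2], src$conc_n[1:2])[(j - 1) * 2 + 1:2]
                   w <- pp * cc / sum(pp * cc)
                   mu <- sum(w * (c(src$mean_d13c, src$mean_d15n)[(j - 1) * 2 + 1:2] + tdf$mean[j]))
                   v <- sum(w^2 * (c(src$sd_d13c, src$sd_d15n)[(j - 1) * 2 + 1:2]^2 + tdf$sd[j]^2))
                   dnorm(y[j], mu, sqrt(v * xi[j]), log = TRUE)
                 })), tolerance = 1e-12)
  }
})

test_that("split R-hat behaves and matches an independent implementation", {
  set.seed(3)
  same <- matrix(rnorm(4 * 2000), 4, 2000)
  expect_lt(rhat(same), 1.01)
  shifted <- rbind(matrix(rnorm(2 * 500), 2, 500), matrix(rnorm(2 * 500, 3), 2, 500))
  expect_gt(rhat(shifted), 1.05)
  expect_warning(expect_true(is.nan(rhat(matrix(1, 2, 10)))), "variance")

  # oracle: independent split R-hat written longhand on a 4 x 1000 fixture
  x <- matrix(rnorm(4000, rep(c(0, 0.2, -0.1, 0.1), 1000)), 4, 1000)
  half <- 500
  sp <- rbind(x[, 1:half], x[, (1000 - half + 1):1000])
  W <- mean(apply(sp, 1, var))
  B <- half * var(rowMeans(sp))
  oracle <- sqrt(((half - 1) / half * W + B / half) / W)
  expect_equal(rhat(x), oracle, tolerance = 1e-12)
})

test_that("mixing polygon inclusion matches a point-in-polygon oracle", {
  src <- make_sources(3)
  tdf <- tdf_spec(c(0, 0), c(0, 0))
  # consumer at the centroid of well-separated sources
  ctr <- matrix(c(mean(src$mean_d13c), mean(src$mean_d15n)), 1)
  pin <- mixing_polygon_check(ctr, src, tdf, n_iter = 300, seed = 1)
  expect_gt(pin, 0.95)
  # consumer far outside
  far <- matrix(c(mean(src$mean_d13c) + 10, mean(src$mean_d15n) + 10), 1)
  expect_lt(mixing_polygon_check(far, src, tdf, n_iter = 300, seed = 1), 0.05)
  expect_warning(mixing_polygon_check(ctr, src, tdf, n_iter = 50, seed = 1), "coarse")

  # fixed-vertex oracle: half-plane test for a triangle
  poly <- rbind(c(0, 0), c(4, 0), c(0, 4))
  inside_oracle <- function(pt) {
    s <- function(a, b) (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
    d1 <- s(poly[1, ], poly[2, ]); d2 <- s(poly[2, ], poly[3, ]); d3 <- s(poly[3, ], poly[1, ])
    (d1 >= 0 && d2 >= 0 && d3 >= 0) || (d1 <= 0 && d2 <= 0 && d3 <= 0)
  }
  set.seed(4)
  pts <- cbind(runif(200, -1, 5), runif(200, -1, 5))
  mine <- apply(pts, 1, isodiet:::.point_in_poly, poly = poly)
  orac <- apply(pts, 1, inside_oracle)
  # boundary-grazing points may differ by tolerance; interior/exterior agree
  off_edge <- abs(pts[, 1]) > 1e-6 & abs(pts[, 2]) > 1e-6 &
    abs(pts[, 1] + pts[, 2] - 4) > 1e-6
  expect_equal(mine[off_edge], orac[off_edge])
})

test_that("the sampler recovers a degenerate near-noiseless diet", {
  src <- make_sources(3, sd = 0.3)
  tdf <- tdf_spec(c(0, 0), c(0.05, 0.05))
  truth <- c(0.5, 0.3, 0.2)
  mm <- mixture_moments(truth, src, tdf)
  set.seed(5)
  n <- 25
  cons <- iso_samples(data.frame(
    sample_id = sprintf("c%02d", 1:n), class = "adult_male", period = "P2000s",
    year = 2000L, d13c = rnorm(n, mm$mean[1], 0.05), d15n = rnorm(n, mm$mean[2], 0.05)),
    "consumer")
  spec <- mixing_model_spec(src, tdf, error_structure = "process_only")
  fit <- fit_mixing_model(spec, cons, chains = 3, iterations = 2500,
                          warmup = 1200, seed = 6)
  expect_true(fit$converged)
  expect_true(all(fit$rhat < 1.05))
  expect_lt(max(abs(colMeans(fit$global_p) - truth)), 0.1)
  # every posterior draw on the simplex
  expect_true(all(abs(rowSums(fit$global_p) - 1) < 1e-9))
  expect_true(all(abs(apply(fit$p, c(1, 2), sum) - 1) < 1e-9))
  expect_true(all(fit$p >= 0))
})

test_that("fixed-effect fits order class diets as simulated", {
  sc <- default_scenarios()$ci_small
  prey <- generate_prey(sc, seed = 20)
  gen <- generate_consumers(sc, seed = 21)
  src <- summarize_sources(prey, NULL, "P2000s")
  spec <- mixing_model_spec(src, sc$tdf, fixed_effect = "class",
                            error_structure = "process_only")
  fit <- suppressWarnings(fit_mixing_model(spec, gen$consumers, chains = 3,
                                           iterations = 2500, warmup = 1250,
                                           seed = 22))
  # class-level mean diets: males eat more source 2 (pelagic) than females
  cls <- gen$consumers$class
  pm_male <- colMeans(fit$p[, cls == "adult_male", 2])
  pm_female <- colMeans(fit$p[, cls == "adult_female", 2])
  expect_gt(mean(pm_male), mean(pm_female))
})

test_that("model spec invariants hold", {
  src <- make_sources(3)
  expect_message(sp <- mixing_model_spec(src, random_individual = TRUE),
                 "process_only")
  expect_equal(sp$error_structure, "process_only")
  expect_error(mixing_model_spec(make_sources(1)), "at least 2")
  # a fixed effect needs at least two covariate levels in the data
  cons1 <- iso_samples(consumer_fixture_df(4), "consumer")  # single year
  expect_error(fit_mixing_model(mixing_model_spec(src, fixed_effect = "year"),
                                cons1, chains = 2, iterations = 50),
               "levels")
})

test_that("prior_posterior_compare summarizes K sources", {
  src <- make_sources(3, sd = 0.5)
  sc <- default_scenarios()$recovery_basic
  gen <- generate_consumers(sc, seed = 30)
  prey <- generate_prey(sc, seed = 31)
  srcs <- summarize_sources(prey, NULL, "P2000s")
  fit <- fit_mixing_model(mixing_model_spec(srcs, sc$tdf), gen$consumers,
                          chains = 3, iterations = 1500, warmup = 700, seed = 32)
  cmp <- prior_posterior_compare(fit)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$prior_mean, rep(1 / 3, 3))
  # informative data: posterior-prior overlap below prior self-overlap (= 1)
  expect_true(all(cmp$overlap < 0.9))
})
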