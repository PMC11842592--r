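test_that("Suess/Laws correction is centered and monotone", {
  for (ry in c(2002, 2020)) {
    sp <- load_suess_params(reference_year = ry)
    expect_equal(suess_correction(ry, sp), 0)
    # declining curve: earlier years get negative corrections
    expect_lt(suess_correction(ry - 7, sp), 0)
    expect_gt(suess_correction(ry + 3, sp), 0)
    # |C| grows with distance from the reference year
    yrs <- (ry - 10):(ry + 5)
    mags <- abs(suess_correction(yrs, sp))
    expect_true(all(diff(mags[yrs < ry]) < 0))
    expect_true(all(diff(mags[yrs > ry]) > 0))
  }
  expect_error(suess_correction(1800, load_suess_params(reference_year = 2002)),
               "range")
})

test_that("Suess correction equals an independent evaluation of the curve", {
  # oracle: re-evaluate the documented drift formula directly from the
  # shipped JSON constants, outside the package code path
  cfg <- jsonlite::read_json(system.file("extdata", "suess_params.json",
                                         package = "isodiet"),
                             simplifyVector = TRUE)
  p <- cfg$regions$north_atlantic
  drift <- function(yr) {
    t <- yr - 1850
    -p$a / p$r_growth * (exp(p$r_growth * t) - 1) + p$laws_sens * p$sst_trend * t
  }
  sp <- load_suess_params(reference_year = 2002)
  expect_equal(suess_correction(1995, sp), drift(2002) - drift(1995),
               tolerance = 1e-12)
  # magnitude is plausibly ~0.02 per-mil/yr over 7 years
  expect_gt(abs(suess_correction(1995, sp)), 0.05)
  expect_lt(abs(suess_correction(1995, sp)), 0.5)
})

test_that("d15N restoration applies per-taxon linear coefficients", {
  expect_equal(restore_bulk_d15n(14.2, "capelin", n15_restoration()), 14.2)
  m <- n15_restoration(data.frame(taxon = "capelin", intercept = -0.5, slope = 1.0))
  expect_equal(restore_bulk_d15n(14.2, "capelin", m), 13.7)
  strict <- n15_restoration(data.frame(taxon = "capelin", intercept = 0, slope = 1),
                            default_identity = FALSE)
  expect_error(restore_bulk_d15n(14.2, "herring", strict), "configuration error")
  expect_error(n15_restoration(data.frame(taxon = "x", intercept = 0, slope = -1)),
               "slope")
})

test_that("apply_corrections composes element-wise and guards re-runs", {
  sp <- load_suess_params(reference_year = 2002)
  cf <- consumer_fixture_df(4)
  cf$year <- c(2002L, 2002L, 1997L, 2000L)
  x <- iso_samples(cf, "consumer")

  out <- apply_corrections(x, sp, n15model = NULL)
  # samples at the reference year unchanged
  expect_equal(out$d13c[1:2], x$d13c[1:2])
  # per-sample corrections equal element-wise calls
  expect_equal(out$d13c, x$d13c + suess_correction(cf$year, sp))
  expect_equal(out$d15n, x$d15n)
  # provenance flag prevents double correction
  expect_error(apply_corrections(out, sp), "already corrected")

  # 2000's samples get both tracers modified, 2020's only d13c
  mixed <- rbind(cf, data.frame(sample_id = "b9", class = "adult_male",
                                period = "P2020s", year = 2019L,
                                d13c = -18, d15n = 15.5))
  mx <- iso_samples(mixed, "consumer")
  n15 <- n15_restoration(data.frame(taxon = "consumer", intercept = 0.4, slope = 1))
  params <- list(P2000s = sp, P2020s = load_suess_params(reference_year = 2020))
  out2 <- apply_corrections(mx, params, n15model = n15)
  audit <- attr(out2, "audit")
  expect_true(all(audit$d15n_restored[mx$period == "P2000s"]))
  expect_false(any(audit$d15n_restored[mx$period == "P2020s"]))
  expect_equal(out2$d15n[5], mx$d15n[5])
  expect_equal(out2$d15n[3], mx$d15n[3] + 0.4)
})
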