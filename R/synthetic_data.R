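# Seeded generator for prey and consumer datasets with the statistical
# structure the analysis assumes: isotopically distinct bivariate-normal prey
# groups, consumers whose diets come from known simplexes with class and year
# effects plus individual ILR random effects, TDF uncertainty, and
# multiplicative residual error. Used by the test suite and the
# parameter-recovery acceptance checks.

#' Define a simulation scenario
#'
#' @param sources data frame with one row per prey group: `group,
#'   mean_d13c, mean_d15n, sd_d13c, sd_d15n, conc_c, conc_n, n` (concentration
#'   as fractions; `n` specimens to draw per group).
#' @param class_diets named list mapping class label to its true K-simplex
#'   diet (in source row order).
#' @param period `"P2000s"` or `"P2020s"`.
#' @param years integer years sampled.
#' @param year_effects optional named list of per-year ILR offset vectors
#'   (length K-1); missing years get zero offset.
#' @param sigma_individual SD of the per-consumer ILR random effect.
#' @param tdf `tdf_spec`.
#' @param error_mult per-tracer multiplicative error inflation (>= 1).
#' @param n_per_cell consumers generated per class x year combination.
#' @param seed default RNG seed for the generators.
#' @return list of class `sim_scenario`.
#' @export
simulation_scenario <- function(sources, class_diets, period = "P2000s",
                                years, year_effects = NULL,
                                sigma_individual = 0.3,
                                tdf = tdf_spec(), error_mult = c(1.5, 1.5),
                                n_per_cell = 3, seed = 42) {
  stopifnot(is.data.frame(sources), nrow(sources) >= 2)
  rownames(sources) <- NULL
  K <- nrow(sources)
  for (d in class_diets) {
    if (length(d) != K || any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop("class diets must be K-simplexes matching the source rows", call. = FALSE)
    }
  }
  if (any(sources$sd_d13c <= 0) || any(sources$sd_d15n <= 0)) {
    stop("source SDs must be > 0", call. = FALSE)
  }
  if (sigma_individual < 0) stop("sigma_individual must be >= 0", call. = FALSE)
  if (any(error_mult < 1)) stop("error_mult must be >= 1", call. = FALSE)
  structure(list(sources = sources, class_diets = class_diets, period = period,
                 years = as.integer(years), year_effects = year_effects,
                 sigma_individual = sigma_individual, tdf = tdf,
                 error_mult = error_mult, n_per_cell = n_per_cell, seed = seed),
            class = "sim_scenario")
}

# scenario sources -> source_summary (what summarize_sources would produce
# at infinite n); used by the forward model
.scenario_source_summary <- function(sc) {
  out <- data.frame(group = sc$sources$group, period = sc$period,
                    n = sc$sources$n,
                    mean_d13c = sc$sources$mean_d13c, mean_d15n = sc$sources$mean_d15n,
                    sd_d13c = sc$sources$sd_d13c, sd_d15n = sc$sources$sd_d15n,
                    conc_c = sc$sources$conc_c, conc_n = sc$sources$conc_n)
  class(out) <- c("source_summary", "data.frame")
  out
}

#' Generate prey specimens from a scenario
#'
#' Per source group, draws `n` specimens with independent normal tracers at
#' the specified means and SDs; elemental percentages get small measurement
#' jitter around the group concentration. Regions cycle over the standard
#' three sampling areas.
#'
#' @param scenario `sim_scenario`.
#' @param seed RNG seed (default from the scenario).
#' @return `iso_samples` of prey.
#' @export
generate_prey <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  sc <- scenario
  rows <- lapply(seq_len(nrow(sc$sources)), function(k) {
    s <- sc$sources[k, ]
    n <- s$n
    yrs <- sc$years[sample.int(length(sc$years), n, replace = TRUE)]
    data.frame(sample_id = sprintf("%s_%03d", s$group, seq_len(n)),
               taxon = s$group, group = s$group,
               region = rep(.regions, length.out = n),
               period = sc$period, year = yrs,
               d13c = stats::rnorm(n, s$mean_d13c, s$sd_d13c),
               d15n = stats::rnorm(n, s$mean_d15n, s$sd_d15n),
               pct_c = pmax(1, s$conc_c * 100 + stats::rnorm(n, 0, 0.5)),
               pct_n = pmax(0.5, s$conc_n * 100 + stats::rnorm(n, 0, 0.2)))
  })
  iso_samples(do.call(rbind, rows), role = "prey")
}

#' Generate consumers with known diets from a scenario
#'
#' Forward model: each consumer's diet is
#' `ilr_inverse(ilr(class diet) + year offset + Normal(0, sigma_individual))`;
#' tracer values are then drawn from
#' `Normal(mixture mean, process variance x error_mult)` using the
#' concentration-dependent mixture moments and the scenario TDF. The realized
#' per-consumer diets are returned as a truth table.
#'
#' @param scenario `sim_scenario`.
#' @param seed RNG seed.
#' @return list: `consumers` (`iso_samples`), `truth` (consumer_id, class,
#'   year, one `p_<group>` column per source).
#' @export
generate_consumers <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  sc <- scenario
  src <- .scenario_source_summary(sc)
  m <- .source_mats(src)
  K <- nrow(src)
  rows <- list(); truths <- list()
  id <- 0L
  for (cl in names(sc$class_diets)) {
    g <- ilr_transform(pmax(sc$class_diets[[cl]], 1e-12) /
                         sum(pmax(sc$class_diets[[cl]], 1e-12)))
    for (yr in sc$years) {
      off <- rep(0, K - 1)
      ye <- sc$year_effects[[as.character(yr)]]
      if (!is.null(ye)) off <- ye
      for (r in seq_len(sc$n_per_cell)) {
        id <- id + 1L
        z <- g + off + stats::rnorm(K - 1, 0, sc$sigma_individual)
        p <- ilr_inverse(z, K)
        mm <- .mixture_moments_mat(matrix(p, 1), m, sc$tdf)
        y <- stats::rnorm(2, mm$mu[1, ], sqrt(mm$s2[1, ] * sc$error_mult))
        rows[[id]] <- data.frame(sample_id = sprintf("C%04d", id), class = cl,
                                 period = sc$period, year = yr,
                                 d13c = y[1], d15n = y[2])
        truths[[id]] <- c(id = id, p)
      }
    }
  }
  consumers <- iso_samples(do.call(rbind, rows), role = "consumer")
  truth <- do.call(rbind, lapply(truths, function(t) t[-1]))
  truth <- as.data.frame(truth)
  names(truth) <- paste0("p_", src$group)
  truth <- cbind(consumers[, c("sample_id", "class", "year")], truth)
  rownames(truth) <- NULL
  list(consumers = consumers, truth = truth)
}

#' Built-in simulation scenarios
#'
#' `paper_like_2000s` and `paper_like_2020s` emulate the structure of the
#' historical and recent sampling periods of the estuarine beluga study
#' system: six (respectively seven, with the striped bass appearing only in
#' the recent period) isotopically distinct prey groups, three sex/age
#' classes with pelagic-dominated (respectively more even) diets, five to six
#' sampling years with small year offsets, individual ILR random effects and
#' multiplicative error. Source geometry is inspired by (not copied from) the
#' published prey isospace. `ci_small` is a fast three-source scenario for
#' continuous integration; `recovery_basic` is the single-class
#' parameter-recovery scenario (true diet 0.6/0.3/0.1, no covariates).
#'
#' @return named list of `sim_scenario`.
#' @export
default_scenarios <- function() {
  tdf <- tdf_spec()
  src6 <- data.frame(
    group = c("groundfish", "tomcod_UE", "pelagic_LE_nwGSL",
              "pelagic_UE", "sand_lance", "smelt_UE"),
    mean_d13c = c(-18.0, -19.5, -20.8, -22.5, -17.2, -21.5),
    mean_d15n = c(16.5, 14.8, 13.2, 12.0, 13.8, 16.0),
    sd_d13c = c(0.8, 0.6, 0.6, 0.7, 0.5, 0.6),
    sd_d15n = c(0.7, 0.6, 0.6, 0.6, 0.5, 0.6),
    conc_c = c(0.45, 0.46, 0.48, 0.47, 0.45, 0.46),
    conc_n = c(0.13, 0.12, 0.11, 0.12, 0.13, 0.12),
    n = c(40, 30, 40, 35, 30, 25))
  src7 <- rbind(src6,
                data.frame(group = "striped_bass_UE", mean_d13c = -16.5,
                           mean_d15n = 17.5, sd_d13c = 0.7, sd_d15n = 0.6,
                           conc_c = 0.46, conc_n = 0.13, n = 30))
  diets_2000s <- list(
    adult_male   = c(0.05, 0.13, 0.05, 0.65, 0.07, 0.05),
    adult_female = c(0.08, 0.06, 0.08, 0.58, 0.15, 0.05),
    juvenile     = c(0.06, 0.06, 0.08, 0.60, 0.14, 0.06))
  diets_2020s <- list(
    adult_male   = c(0.20, 0.08, 0.22, 0.12, 0.08, 0.20, 0.10),
    adult_female = c(0.10, 0.07, 0.24, 0.14, 0.20, 0.17, 0.08),
    juvenile     = c(0.08, 0.07, 0.23, 0.13, 0.22, 0.17, 0.10))
  ye_2020s <- list(`2020` = c(0.3, -0.2, 0.1, 0, 0, 0))
  list(
    paper_like_2000s = simulation_scenario(
      src6, diets_2000s, period = "P2000s", years = 1997:2003,
      sigma_individual = 0.25, tdf = tdf, error_mult = c(1.5, 1.5),
      n_per_cell = 3, seed = 42),
    paper_like_2020s = simulation_scenario(
      src7, diets_2020s, period = "P2020s", years = 2015:2020,
      year_effects = ye_2020s, sigma_individual = 0.35, tdf = tdf,
      error_mult = c(1.5, 1.5), n_per_cell = 3, seed = 43),
    ci_small = simulation_scenario(
      src6[c(1, 4, 5), ], list(adult_male = c(0.2, 0.6, 0.2),
                               adult_female = c(0.3, 0.4, 0.3)),
      period = "P2000s", years = 2000:2002, sigma_individual = 0.2,
      tdf = tdf, error_mult = c(1, 1), n_per_cell = 3, seed = 7),
    recovery_basic = simulation_scenario(
      src6[c(1, 4, 5), ], list(adult_male = c(0.6, 0.3, 0.1)),
      period = "P2000s", years = 2000L, sigma_individual = 0,
      tdf = tdf, error_mult = c(1, 1), n_per_cell = 30, seed = 11))
}

#' Serialize / deserialize a scenario
#'
#' @param scenario `sim_scenario`.
#' @param path JSON file path.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$tdf <- unclass(x$tdf)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class_diets <- lapply(x$class_diets, as.numeric)
  year_effects <- if (!is.null(x$year_effects) && length(x$year_effects)) {
    lapply(x$year_effects, as.numeric)
  } else NULL
  simulation_scenario(as.data.frame(x$sources), class_diets, period = x$period,
                      years = x$years, year_effects = year_effects,
                      sigma_individual = x$sigma_individual,
                      tdf = tdf_spec(x$tdf$mean, x$tdf$sd),
                      error_mult = x$error_mult, n_per_cell = x$n_per_cell,
                      seed = x$seed)
}
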