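# Temporal and analytical corrections applied before mixing-model fitting:
# the oceanic Suess effect (fossil-fuel-driven secular decline in d13C) plus
# the temperature-dependent Laws modulation, and restoration of bulk d15N for
# historical samples whose nitrogen was measured on lipid-extracted tissue.

#' Suess/Laws correction parameters
#'
#' The secular \eqn{\delta^{13}}C drift is modelled as an exponentially
#' accelerating annual decline (the atmospheric Suess signal propagated into
#' the ocean) plus a linear sea-surface-temperature term (the Laws effect on
#' aqueous CO2 and phytoplankton fractionation):
#' \deqn{T(t) = -\frac{a}{b}\left(e^{b (t - 1850)} - 1\right) + c\, m (t - 1850)}
#' where \eqn{a} (per mil/yr) is the annual decline rate at 1850, \eqn{b}
#' (1/yr) its exponential growth rate, \eqn{m} (deg C/yr) the regional SST
#' trend and \eqn{c} (per mil/deg C) the Laws sensitivity. Corrections are
#' differences of \eqn{T} centered on a reference year. The shipped North
#' Atlantic preset is reconstructed from the published regional rates (about
#' -0.02 per mil/yr in recent decades), not copied from any package source.
#'
#' @param reference_year year at which the correction is exactly zero
#'   (2002 for the 2000's period, 2020 for the 2020's period).
#' @param region region label (bookkeeping only).
#' @param a,b,r_growth,sst_trend,laws_sens curve constants; see above
#'   (`r_growth` = b, `sst_trend` = m, `laws_sens` = c).
#' @return list of class `suess_params`.
#' @export
suess_params <- function(reference_year, region = "North Atlantic",
                         a = 3.83e-4, r_growth = 0.027,
                         sst_trend = 0.005, laws_sens = -0.3, b = NULL) {
  if (!is.null(b)) r_growth <- b
  stopifnot(is.numeric(reference_year), length(reference_year) == 1)
  if (a < 0 || r_growth <= 0) stop("need a >= 0 and r_growth > 0", call. = FALSE)
  structure(list(region = region, reference_year = as.integer(reference_year),
                 a = a, r_growth = r_growth,
                 sst_trend = sst_trend, laws_sens = laws_sens),
            class = "suess_params")
}

#' Load Suess/Laws regional presets from JSON
#'
#' @param path JSON file; defaults to the preset file shipped with the package.
#' @param region preset name.
#' @param reference_year centering year.
#' @return `suess_params` object.
#' @export
load_suess_params <- function(region = "north_atlantic", reference_year,
                              path = system.file("extdata", "suess_params.json",
                                                 package = "isodiet")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!region %in% names(cfg$regions)) {
    stop("no preset for region '", region, "'", call. = FALSE)
  }
  p <- cfg$regions[[region]]
  suess_params(reference_year, region = region, a = p$a, r_growth = p$r_growth,
               sst_trend = p$sst_trend, laws_sens = p$laws_sens)
}

# cumulative drift since 1850 (per mil); negative and decreasing in year
.suess_drift <- function(year, params) {
  t <- year - 1850
  -params$a / params$r_growth * (exp(params$r_growth * t) - 1) +
    params$laws_sens * params$sst_trend * t
}

#' Suess + Laws additive correction for one or more years
#'
#' Returns `C(year)` such that corrected d13c = raw d13c + `C(year)`.
#' `C(reference_year) = 0`; under the declining default curve, samples from
#' years before the reference year receive a negative correction (they were
#' measured in a heavier-carbon ocean than the reference year) and later
#' samples a positive one.
#'
#' @param year integer year(s) in 1850-2025.
#' @param params `suess_params`.
#' @return per-mil additive correction(s).
#' @export
suess_correction <- function(year, params) {
  stopifnot(inherits(params, "suess_params"))
  if (any(year < 1850 | year > 2025)) {
    stop("year outside supported range 1850-2025", call. = FALSE)
  }
  .suess_drift(params$reference_year, params) - .suess_drift(year, params)
}

#' Bulk d15N restoration model for lipid-extracted samples
#'
#' Per-taxon linear maps `bulk = intercept + slope * lipid_extracted` used to
#' recover bulk-tissue d15N from measurements made on lipid-extracted aliquots
#' (the 2000's protocol). Coefficients are supplied by the user (they are
#' calibration-specific); the default is the identity map.
#'
#' @param coef data frame with columns `taxon, intercept, slope`, or `NULL`
#'   for identity-only.
#' @param default_identity if `TRUE`, taxa without coefficients fall back to
#'   the identity map; if `FALSE` they are a configuration error.
#' @return list of class `n15_restoration`.
#' @export
n15_restoration <- function(coef = NULL, default_identity = TRUE) {
  if (!is.null(coef)) {
    stopifnot(all(c("taxon", "intercept", "slope") %in% names(coef)))
    if (any(coef$slope <= 0)) stop("restoration slope must be > 0", call. = FALSE)
  }
  structure(list(coef = coef, default_identity = default_identity),
            class = "n15_restoration")
}

#' @rdname n15_restoration
#' @param d15n_lipid_extracted measured per-mil value(s).
#' @param taxon taxon label (scalar).
#' @param model `n15_restoration`.
#' @export
restore_bulk_d15n <- function(d15n_lipid_extracted, taxon, model) {
  stopifnot(inherits(model, "n15_restoration"))
  cf <- NULL
  if (!is.null(model$coef)) {
    hit <- model$coef[model$coef$taxon == taxon, , drop = FALSE]
    if (nrow(hit) >= 1) cf <- c(hit$intercept[1], hit$slope[1])
  }
  if (is.null(cf)) {
    if (!model$default_identity) {
      stop("configuration error: no d15N restoration coefficients for taxon '",
           taxon, "'", call. = FALSE)
    }
    cf <- c(0, 1)
  }
  cf[1] + cf[2] * d15n_lipid_extracted
}

#' Apply temporal and analytical corrections to a sample set
#'
#' Adjusts `d13c` by the Suess/Laws correction for each sample's year, and
#' restores bulk `d15n` for samples flagged as nitrogen-measured on
#' lipid-extracted tissue (by default, all samples from the 2000's period,
#' matching the historical protocol; 2020's samples had nitrogen measured on
#' untreated aliquots and only their d13c is adjusted). A provenance flag
#' guards against double correction.
#'
#' @param samples `iso_samples`.
#' @param params `suess_params` (or a named list of them keyed by period, so
#'   each period is centered on its own reference year).
#' @param n15model optional `n15_restoration`; `NULL` skips restoration.
#' @param lipid_extracted_n logical vector marking which samples need d15n
#'   restoration; default flags the 2000's period, or uses an
#'   `n15_lipid_extracted` column when present.
#' @return corrected `iso_samples`; attribute `audit` is a data frame of
#'   per-sample adjustments.
#' @export
apply_corrections <- function(samples, params, n15model = NULL,
                              lipid_extracted_n = NULL) {
  if (isTRUE(attr(samples, "corrected"))) {
    stop("samples already corrected (provenance flag set); refusing to re-run",
         call. = FALSE)
  }
  if (inherits(params, "suess_params")) {
    per_period <- stats::setNames(rep(list(params), length(.periods)), .periods)
  } else {
    per_period <- params
    stopifnot(all(unique(samples$period) %in% names(per_period)))
  }
  if (is.null(lipid_extracted_n)) {
    lipid_extracted_n <- if ("n15_lipid_extracted" %in% names(samples)) {
      as.logical(samples$n15_lipid_extracted)
    } else {
      samples$period == "P2000s"
    }
  }
  d13c_adj <- vapply(seq_len(nrow(samples)), function(i) {
    suess_correction(samples$year[i], per_period[[samples$period[i]]])
  }, numeric(1))
  d15n_new <- samples$d15n
  if (!is.null(n15model)) {
    tx <- if ("taxon" %in% names(samples)) samples$taxon else rep("consumer", nrow(samples))
    for (i in which(lipid_extracted_n)) {
      d15n_new[i] <- restore_bulk_d15n(samples$d15n[i], tx[i], n15model)
    }
  }
  audit <- data.frame(sample_id = samples$sample_id, year = samples$year,
                      d13c_correction = d13c_adj,
                      d15n_restored = !is.null(n15model) & lipid_extracted_n,
                      d15n_shift = d15n_new - samples$d15n)
  samples$d13c <- samples$d13c + d13c_adj
  samples$d15n <- d15n_new
  attr(samples, "corrected") <- TRUE
  attr(samples, "audit") <- audit
  samples
}
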