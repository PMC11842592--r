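#' isodiet: Bayesian stable-isotope diet analysis
#'
#' Estimates consumer diet composition from bulk \eqn{\delta^{13}}C and
#' \eqn{\delta^{15}}N measurements of consumers and their potential prey,
#' with temporal isotope corrections, permutation multivariate statistics,
#' a concentration-dependent Bayesian mixing model, information-criterion
#' model selection, and individual-level diet metrics.
#'
#' @keywords internal
"_PACKAGE"

# ---- validation bounds (warnings by default, errors under strict) ----------

.iso_bounds <- list(d13c = c(-40, -10), d15n = c(0, 25))

.periods <- c("P2000s", "P2020s")
.classes <- c("adult_male", "adult_female", "juvenile")
.regions <- c("UE", "LE", "nwGSL")

# calendar ranges for the two sampling periods
.period_years <- list(P2000s = c(1995L, 2003L), P2020s = c(2015L, 2020L))

#' Convert isotope ratios to delta notation
#'
#' \eqn{\delta X = (R_{sample}/R_{standard} - 1) \times 1000}, the per-mil
#' deviation of a sample isotope ratio from an international standard
#' (VPDB for carbon, atmospheric N2 for nitrogen).
#'
#' @param r_sample sample isotope ratio(s), nonnegative.
#' @param r_standard standard isotope ratio(s), strictly positive.
#' @return per-mil delta value(s).
#' @seealso [ratio_from_delta()] for the inverse.
#' @export
#' @examples
#' delta_from_ratio(0.0112372 * 1.01, 0.0112372)  # 10 per mil
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("r_standard must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(r_sample)) || any(r_sample < 0)) {
    stop("r_sample must be finite and >= 0", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' @rdname delta_from_ratio
#' @param delta per-mil delta value(s).
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("r_standard must be finite and > 0", call. = FALSE)
  }
  (delta / 1000 + 1) * r_standard
}

# ---- sample container ------------------------------------------------------

#' Construct a set of isotope samples
#'
#' An `iso_samples` object is a data frame of specimen records, one row per
#' sample, carrying tracer values and metadata. Consumers need
#' `sample_id, class, period, year, d13c, d15n`; prey additionally need
#' `taxon, group, region, pct_c, pct_n`.
#'
#' @param df data frame of records.
#' @param role `"consumer"` or `"prey"`.
#' @param strict if `TRUE`, validation-bound violations are errors rather
#'   than warnings.
#' @return data frame of class `iso_samples`.
#' @export
iso_samples <- function(df, role = c("consumer", "prey"), strict = FALSE) {
  role <- match.arg(role)
  req <- c("sample_id", "period", "year", "d13c", "d15n")
  if (role == "consumer") req <- c(req, "class")
  if (role == "prey")     req <- c(req, "taxon", "group", "region", "pct_c", "pct_n")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df$period <- as.character(df$period)
  bad_period <- !df$period %in% .periods
  if (any(bad_period)) {
    stop("unknown period value(s): ", paste(unique(df$period[bad_period]), collapse = ", "),
         " (expected ", paste(.periods, collapse = "/"), ")", call. = FALSE)
  }
  if (role == "consumer") {
    bad_class <- !df$class %in% .classes
    if (any(bad_class)) {
      stop("unknown class value(s): ", paste(unique(df$class[bad_class]), collapse = ", "),
           call. = FALSE)
    }
  }
  if (role == "prey") {
    bad_region <- !df$region %in% .regions
    if (any(bad_region)) {
      stop("unknown region value(s): ", paste(unique(df$region[bad_region]), collapse = ", "),
           call. = FALSE)
    }
  }
  df$year <- as.integer(df$year)
  .validate_tracers(df, strict = strict)
  .validate_years(df, strict = strict)
  df$role <- rep(role, nrow(df))
  class(df) <- c("iso_samples", "data.frame")
  df
}

.validate_tracers <- function(df, strict = FALSE) {
  flag <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      rows <- which(cond)
      text <- sprintf("%s in row(s) %s", msg, paste(utils::head(rows, 5), collapse = ", "))
      if (strict) stop(text, call. = FALSE) else warning(text, call. = FALSE)
    }
  }
  b <- .iso_bounds
  flag(df$d13c < b$d13c[1] | df$d13c > b$d13c[2],
       sprintf("d13c outside [%g, %g]", b$d13c[1], b$d13c[2]))
  flag(df$d15n < b$d15n[1] | df$d15n > b$d15n[2],
       sprintf("d15n outside [%g, %g]", b$d15n[1], b$d15n[2]))
  invisible(df)
}

.validate_years <- function(df, strict = FALSE) {
  for (p in unique(df$period)) {
    rng <- .period_years[[p]]
    bad <- df$period == p & (df$year < rng[1] | df$year > rng[2])
    if (any(bad)) {
      text <- sprintf("year outside %d-%d for period %s in row(s) %s",
                      rng[1], rng[2], p,
                      paste(utils::head(which(bad), 5), collapse = ", "))
      if (strict) stop(text, call. = FALSE) else warning(text, call. = FALSE)
    }
  }
  invisible(df)
}

#' Read consumer or prey isotope records from CSV
#'
#' Expects UTF-8 comma-separated files with one header row and period decimal
#' marks. Rows failing to parse are rejected with row-level diagnostics; the
#' remainder are returned.
#'
#' Consumer schema: `sample_id,class,period,year,d13c,d15n`
#' (optional `n15_lipid_extracted` logical column).
#' Prey schema: `sample_id,taxon,group,region,period,year,d13c,d15n,pct_c,pct_n`.
#'
#' @param path CSV file path.
#' @param schema `"consumer"` or `"prey"`.
#' @param strict escalate validation warnings to errors.
#' @return `iso_samples` data frame; attribute `rejected` holds diagnostics
#'   for dropped rows.
#' @export
read_samples <- function(path, schema = c("consumer", "prey"), strict = FALSE) {
  schema <- match.arg(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- if (schema == "consumer") {
    c("sample_id", "class", "period", "year", "d13c", "d15n")
  } else {
    c("sample_id", "taxon", "group", "region", "period", "year",
      "d13c", "d15n", "pct_c", "pct_n")
  }
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("empty file (header only): ", path, call. = FALSE)
  }
  num_cols <- intersect(c("year", "d13c", "d15n", "pct_c", "pct_n"), req)
  rejected <- character(0)
  keep <- rep(TRUE, nrow(raw))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- is.na(v)
    if (any(bad)) {
      rejected <- c(rejected, sprintf("row %d: unparseable or missing %s (%s)",
                                      which(bad), cl, as.character(raw[[cl]][bad])))
      keep <- keep & !bad
    }
    raw[[cl]] <- v
  }
  if (length(rejected)) {
    warning(sprintf("%d row(s) rejected in %s:\n%s", sum(!keep), path,
                    paste(utils::head(rejected, 10), collapse = "\n")), call. = FALSE)
  }
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("read %d %s record(s) from %s (%d rejected)",
                  nrow(out), schema, path, sum(!keep)))
  out <- iso_samples(out, role = schema, strict = strict)
  attr(out, "rejected") <- rejected
  out
}

#' Write isotope samples to CSV
#'
#' @param x `iso_samples` (or plain data frame).
#' @param path output path.
#' @export
write_samples <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- source summaries ------------------------------------------------------

#' Summarize prey isotope records into mixing-model sources
#'
#' Aggregates prey taxa into functional groups and computes, per group and
#' tracer, the sample mean, sample SD (n-1 denominator) and mean elemental
#' concentration (from `pct_c`/`pct_n`, as fractions). These summaries are the
#' fixed source parameters of the mixing model.
#'
#' @param prey `iso_samples` of prey records.
#' @param grouping named character vector mapping taxon to group label; if
#'   `NULL`, the `group` column of `prey` is used directly.
#' @param period restrict to one period (`"P2000s"` or `"P2020s"`).
#' @return data frame of class `source_summary` with one row per group:
#'   `group, period, n, mean_d13c, mean_d15n, sd_d13c, sd_d15n, conc_c, conc_n`.
#' @export
summarize_sources <- function(prey, grouping = NULL, period) {
  stopifnot(period %in% .periods)
  prey <- prey[prey$period == period, , drop = FALSE]
  if (nrow(prey) == 0) stop("no prey records for period ", period, call. = FALSE)
  if (!is.null(grouping)) {
    unmapped <- setdiff(unique(prey$taxon), names(grouping))
    if (length(unmapped)) {
      stop("configuration error: unmapped taxon/taxa: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    prey$group <- unname(grouping[prey$taxon])
  }
  groups <- sort(unique(prey$group))
  rows <- lapply(groups, function(g) {
    sub <- prey[prey$group == g, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) {
      stop(sprintf("degenerate group '%s': n = %d < 2 in period %s", g, n, period),
           call. = FALSE)
    }
    sdc <- stats::sd(sub$d13c); sdn <- stats::sd(sub$d15n)
    if (sdc <= 0 || sdn <= 0) {
      stop(sprintf("degenerate group '%s': zero tracer SD", g), call. = FALSE)
    }
    data.frame(group = g, period = period, n = n,
               mean_d13c = mean(sub$d13c), mean_d15n = mean(sub$d15n),
               sd_d13c = sdc, sd_d15n = sdn,
               conc_c = mean(sub$pct_c) / 100, conc_n = mean(sub$pct_n) / 100)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$conc_c <= 0 | out$conc_c > 1 | out$conc_n <= 0 | out$conc_n > 1)) {
    stop("elemental concentrations must lie in (0, 1] after pct -> fraction conversion",
         call. = FALSE)
  }
  class(out) <- c("source_summary", "data.frame")
  out
}

#' Trophic discrimination factor specification
#'
#' Mean tissue-diet isotopic offset and its SD for the two tracers
#' (carbon first, nitrogen second). Defaults are the muscle values used for
#' odontocetes lacking species-specific calibrations:
#' \eqn{\Delta^{13}C = 1.3 \pm 0.5}, \eqn{\Delta^{15}N = 2.4 \pm 0.5}.
#'
#' @param mean length-2 per-mil vector `(d13c, d15n)`.
#' @param sd length-2 nonnegative per-mil vector.
#' @return list of class `tdf_spec`.
#' @export
tdf_spec <- function(mean = c(1.3, 2.4), sd = c(0.5, 0.5)) {
  stopifnot(length(mean) == 2, length(sd) == 2)
  if (any(sd < 0)) stop("tdf sd must be >= 0", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)), class = "tdf_spec")
}

# internal: source_summary -> matrices used by the mixing model
.source_mats <- function(sources) {
  list(mu   = cbind(sources$mean_d13c, sources$mean_d15n),
       sd   = cbind(sources$sd_d13c, sources$sd_d15n),
       conc = cbind(sources$conc_c, sources$conc_n),
       labels = sources$group)
}
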