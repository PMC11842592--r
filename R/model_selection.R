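# Predictive-accuracy model comparison on the deviance scale: WAIC and
# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO), computed from the draws x consumers pointwise log-likelihood
# matrix. The pointwise unit is one consumer (both tracers jointly), matching
# the likelihood factorization.

.log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' `lppd_i = log mean_s exp(ll_si)`; `p_waic_i = var_s(ll_si)` (n-1
#' denominator); `waic = -2 * sum_i (lppd_i - p_waic_i)`. The standard error
#' is `sqrt(n * var_i(waic_i))` over the pointwise contributions.
#'
#' @param loglik draws x consumers matrix of pointwise log-likelihoods.
#' @return list: `waic`, `se`, `p_waic`, `pointwise` (per-consumer elpd).
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(loglik))) {
    bad <- which(colSums(!is.finite(loglik)) > 0)
    stop("non-finite log-likelihood for consumer(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  S <- nrow(loglik)
  lppd_i <- apply(loglik, 2, .log_sum_exp) - log(S)
  p_i <- apply(loglik, 2, stats::var)
  elpd_i <- lppd_i - p_i
  pointwise <- -2 * elpd_i
  list(waic = sum(pointwise), se = sqrt(length(elpd_i) * stats::var(pointwise)),
       p_waic = sum(p_i), pointwise = elpd_i, lppd = sum(lppd_i))
}

# Zhang-Stephens (2009) empirical-Bayes generalized Pareto fit with the
# usual small-sample shrinkage of k toward 0.5 (weight 10)
.gpd_fit <- function(x, shrink_k = TRUE) {
  x <- sort.int(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = NaN, sigma = NaN))
  M <- 30 + floor(sqrt(n))
  jj <- seq_len(M)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[n] / 2
  theta <- 1 / x[n] + (1 - sqrt(M / (jj - 0.5))) / (3 * xstar)
  k_of <- vapply(theta, function(th) -mean(log1p(-th * x)), numeric(1))
  l_theta <- n * (log(theta / k_of) + k_of - 1)
  w <- exp(l_theta - .log_sum_exp(l_theta))
  theta_hat <- sum(theta * w)
  kz <- -mean(log1p(-theta_hat * x))   # Zhang-Stephens k = -xi
  sigma <- kz / theta_hat
  k <- -kz                             # GPD tail index xi (positive = heavy)
  if (shrink_k) k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# smooth one vector of log importance ratios; returns list(lw, k)
.psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || stats::sd(lw) < 1e-12) {
    return(list(lw = lw, k = 0, smoothed = FALSE))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_idx]) - cutoff
  fit <- .gpd_fit(exceed)
  if (!is.finite(fit$k)) {
    return(list(lw = lw, k = NaN, smoothed = FALSE))
  }
  qs <- vapply((seq_len(M) - 0.5) / M, .qgpd, numeric(1), k = fit$k, sigma = fit$sigma)
  new_tail <- log(qs + cutoff)
  # keep order statistics aligned with the original tail ordering
  lw[tail_idx[order(lw[tail_idx])]] <- pmin(new_tail, 0)
  list(lw = lw, k = fit$k, smoothed = TRUE)
}

#' PSIS leave-one-out cross-validation
#'
#' Raw importance ratios for consumer i are `r_s = exp(-ll_si)`; the largest
#' 20% are replaced by expected order statistics of a generalized Pareto
#' distribution fitted to the tail (Pareto-smoothed importance sampling), and
#' `elpd_loo_i = log( sum_s w_s exp(ll_si) / sum_s w_s )`. Consumers whose
#' tail shape `k > 0.7` are counted as reliability warnings. Degenerate
#' all-equal ratios fall back to plain importance sampling with a notice.
#'
#' @param loglik draws x consumers matrix.
#' @return list: `looic`, `se`, `pareto_k` (per consumer), `n_warnings`,
#'   `pointwise` (per-consumer elpd_loo).
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  S <- nrow(loglik)
  if (S < 2) stop("need at least 2 draws", call. = FALSE)
  if (S < 100) warning("fewer than 100 draws: PSIS tail fit is unreliable", call. = FALSE)
  n <- ncol(loglik)
  elpd <- numeric(n); kk <- numeric(n)
  fallback <- 0L
  for (i in seq_len(n)) {
    sm <- .psis_smooth(-loglik[, i])
    if (!isTRUE(sm$smoothed)) fallback <- fallback + 1L
    lw <- sm$lw
    elpd[i] <- .log_sum_exp(lw + loglik[, i]) - .log_sum_exp(lw)
    kk[i] <- sm$k
  }
  if (fallback > 0) {
    message(fallback, " consumer(s) used plain importance sampling (degenerate ratios)")
  }
  pointwise <- -2 * elpd
  list(looic = sum(pointwise), se = sqrt(n * stats::var(pointwise)),
       pareto_k = kk, n_warnings = sum(is.finite(kk) & kk > 0.7),
       pointwise = elpd)
}

#' Score a fitted mixing model
#'
#' @param fit `mix_fit`.
#' @param model_label label for the ranking table (default from the spec).
#' @param period period label.
#' @return one-row data frame of class `model_score`.
#' @export
score_model <- function(fit, model_label = NULL, period = NA_character_) {
  w <- waic(fit$loglik_pointwise)
  l <- psis_loo(fit$loglik_pointwise)
  out <- data.frame(model = model_label %||% model_label(fit$spec),
                    period = period,
                    looic = l$looic, looic_se = l$se,
                    waic = w$waic, waic_se = w$se,
                    p_waic = w$p_waic,
                    pareto_k_warnings = l$n_warnings,
                    error_term = fit$spec$error_structure,
                    converged = fit$converged)
  class(out) <- c("model_score", "data.frame")
  out
}

#' Rank candidate models per period
#'
#' Computes, within each period, differences from the best (lowest) LOOic and
#' WAIC, and sorts by LOOic then WAIC (stable).
#'
#' @param scores data frame of model scores (rows from [score_model()] or the
#'   same columns).
#' @return data frame with `delta_looic` and `delta_waic` columns added.
#' @export
rank_models <- function(scores) {
  scores <- as.data.frame(scores)
  if (nrow(scores) == 0) stop("no scores", call. = FALSE)
  if (length(unique(scores$period)) > 1 && anyNA(scores$period)) {
    stop("mixed periods without period labels", call. = FALSE)
  }
  parts <- split(scores, scores$period, drop = TRUE)
  out <- lapply(parts, function(s) {
    s$delta_looic <- s$looic - min(s$looic)
    s$delta_waic <- s$waic - min(s$waic)
    s[order(s$looic, s$waic), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
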