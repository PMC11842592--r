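# Bayesian concentration-dependent stable-isotope mixing model.
#
# Diet proportions live on the K-simplex; covariate structure (fixed class or
# year effects, individual random effects) is placed on isometric log-ratio
# (ILR) coordinates. The observation model for tracer j of consumer i is
#   y_ij ~ Normal(mu_ij, sigma2_ij * xi_j)
# with mixture mean/variance from concentration-weighted source contributions
# shifted by trophic discrimination factors, and xi_j a tracer-specific
# multiplicative ("residual x process") error inflation; xi_j = 1 recovers
# the process-only model. Sampling is blockwise adaptive random-walk
# Metropolis over unconstrained coordinates (ILR, log-sigma, log-xi).

# ---- ILR machinery ---------------------------------------------------------

# orthonormal (Helmert-type) ILR basis, K x (K-1); column j contrasts the
# geometric mean of parts 1..j against part j+1
.ilr_basis <- function(K) {
  V <- matrix(0, K, K - 1)
  for (j in seq_len(K - 1)) {
    V[seq_len(j), j] <- 1 / sqrt(j * (j + 1))
    V[j + 1, j] <- -j / sqrt(j * (j + 1))
  }
  V
}

#' Isometric log-ratio transform and inverse
#'
#' Maps a strictly positive K-part composition to unconstrained (K-1)-space
#' using a fixed orthonormal basis (column j contrasts the geometric mean of
#' parts 1..j against part j+1; for K = 2 the single coordinate is
#' `(1/sqrt(2)) * log(p1/p2)`). The inverse renormalizes through the softmax
#' of the compositional (clr) coordinates.
#'
#' @param p K-simplex vector (strictly positive, sums to 1).
#' @return `(K-1)`-vector of ILR coordinates.
#' @export
ilr_transform <- function(p) {
  if (any(p <= 0)) stop("zero or negative component: ILR undefined", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1", call. = FALSE)
  drop(crossprod(.ilr_basis(length(p)), log(p)))
}

#' @rdname ilr_transform
#' @param z `(K-1)`-vector of ILR coordinates.
#' @param K number of parts.
#' @export
ilr_inverse <- function(z, K = length(z) + 1) {
  e <- exp(.ilr_basis(K) %*% z)
  drop(e / sum(e))
}

# rows of Z -> rows of P (n x K), vectorized
.ilr_inverse_mat <- function(Z, K) {
  E <- exp(Z %*% t(.ilr_basis(K)))
  E / rowSums(E)
}

# ---- mixture moments and likelihood ---------------------------------------

#' Concentration-dependent mixture moments
#'
#' For tracer j, contributions are weighted by diet proportion times source
#' elemental concentration: `w_k = p_k c_kj / sum_m p_m c_mj`. The mixture
#' mean adds the trophic discrimination factor to each source mean, and the
#' process variance propagates source and TDF variances with squared weights:
#' \deqn{\mu_j = \sum_k w_k (\mu_{kj} + \Delta_j), \quad
#'       \sigma^2_j = \sum_k w_k^2 (\tau_{kj}^2 + \delta_j^2).}
#'
#' @param p K-simplex of diet proportions.
#' @param sources `source_summary` data frame (K rows).
#' @param tdf `tdf_spec`.
#' @return list with `mean` and `var`, each length-2 (d13c, d15n).
#' @export
mixture_moments <- function(p, sources, tdf) {
  m <- .source_mats(sources)
  if (any(colSums(p * m$conc) <= 0)) {
    stop("zero total elemental concentration", call. = FALSE)
  }
  out_mean <- numeric(2); out_var <- numeric(2)
  for (j in 1:2) {
    w <- p * m$conc[, j]
    w <- w / sum(w)
    out_mean[j] <- sum(w * (m$mu[, j] + tdf$mean[j]))
    out_var[j] <- sum(w^2 * (m$sd[, j]^2 + tdf$sd[j]^2))
  }
  list(mean = out_mean, var = out_var)
}

# vectorized moments for an n x K proportion matrix; returns mu, s2 (n x 2)
.mixture_moments_mat <- function(P, m, tdf) {
  n <- nrow(P); K <- ncol(P)
  mu <- matrix(0, n, 2); s2 <- matrix(0, n, 2)
  for (j in 1:2) {
    W <- P * matrix(m$conc[, j], n, K, byrow = TRUE)
    W <- W / rowSums(W)
    mu[, j] <- W %*% (m$mu[, j] + tdf$mean[j])
    s2[, j] <- (W * W) %*% (m$sd[, j]^2 + tdf$sd[j]^2)
  }
  list(mu = mu, s2 = s2)
}

#' Mixing-model log-likelihood of one consumer
#'
#' Sum over the two tracers of the normal log-density at the
#' concentration-dependent mixture moments, with observation variance
#' `sigma2_j * xi_j` (multiplicative error). `error_mult = c(1, 1)` gives the
#' process-only likelihood.
#'
#' @param y length-2 observed tracer values `(d13c, d15n)`.
#' @param p diet simplex.
#' @param sources `source_summary`.
#' @param tdf `tdf_spec`.
#' @param error_mult per-tracer variance multipliers (> 0).
#' @return scalar log-likelihood.
#' @export
mix_loglik <- function(y, p, sources, tdf, error_mult = c(1, 1)) {
  if (any(!is.finite(y))) stop("non-finite tracer value", call. = FALSE)
  if (any(error_mult <= 0)) stop("error_mult must be > 0", call. = FALSE)
  mm <- mixture_moments(p, sources, tdf)
  sum(stats::dnorm(y, mm$mean, sqrt(mm$var * error_mult), log = TRUE))
}

# full pointwise log-likelihood for consumer ILR matrix Z (n x (K-1))
.loglik_rows <- function(Z, y, m, tdf, xi, K) {
  P <- .ilr_inverse_mat(Z, K)
  mm <- .mixture_moments_mat(P, m, tdf)
  stats::dnorm(y[, 1], mm$mu[, 1], sqrt(mm$s2[, 1] * xi[1]), log = TRUE) +
    stats::dnorm(y[, 2], mm$mu[, 2], sqrt(mm$s2[, 2] * xi[2]), log = TRUE)
}

# ---- model specification ---------------------------------------------------

#' Specify a mixing model
#'
#' @param sources `source_summary` (K >= 2 rows, one period).
#' @param tdf `tdf_spec`.
#' @param fixed_effect `NULL`, `"class"`, `"year"`, or `"class_x_year"`
#'   (additive crossed class + year effects).
#' @param random_individual include a per-consumer random effect on the ILR
#'   scale, `u_i ~ Normal(0, sigma_ind)` with a single shared SD.
#' @param error_structure `"residual_x_process"` (tracer-specific
#'   multiplicative variance inflation `xi_j`) or `"process_only"`
#'   (`xi_j = 1`). When the individual random effect is the only covariate the
#'   error structure is forced to `"process_only"`: with one observation per
#'   individual the multiplicative term is not identifiable alongside it.
#' @param prior_alpha Dirichlet concentration for the global diet prior
#'   (scalar or length-K; default 1, non-informative).
#' @param prior_sd_fixed Normal prior SD for fixed-effect ILR offsets.
#' @param prior_sd_sigma half-Normal prior scale for `sigma_ind`.
#' @return list of class `mixing_model_spec`.
#' @export
mixing_model_spec <- function(sources, tdf = tdf_spec(),
                              fixed_effect = NULL,
                              random_individual = FALSE,
                              error_structure = c("residual_x_process", "process_only"),
                              prior_alpha = 1,
                              prior_sd_fixed = 2,
                              prior_sd_sigma = 2) {
  error_structure <- match.arg(error_structure)
  K <- nrow(sources)
  if (K < 2) stop("need at least 2 sources", call. = FALSE)
  if (!is.null(fixed_effect)) {
    fixed_effect <- match.arg(fixed_effect, c("class", "year", "class_x_year"))
  }
  if (random_individual && is.null(fixed_effect) &&
      error_structure == "residual_x_process") {
    message("individual-only model: forcing process_only error structure")
    error_structure <- "process_only"
  }
  alpha <- if (length(prior_alpha) == 1) rep(prior_alpha, K) else prior_alpha
  stopifnot(length(alpha) == K, all(alpha > 0))
  structure(list(sources = sources, tdf = tdf, K = K,
                 fixed_effect = fixed_effect,
                 random_individual = random_individual,
                 error_structure = error_structure,
                 prior_alpha = alpha,
                 prior_sd_fixed = prior_sd_fixed,
                 prior_sd_sigma = prior_sd_sigma),
            class = "mixing_model_spec")
}

#' Canonical label for a candidate model
#'
#' Mirrors the candidate-model naming scheme used when ranking the eight
#' standard models per period (e.g. `"class+ind"`, `"year"`, `"null"`).
#'
#' @param spec `mixing_model_spec`.
#' @return character label.
#' @export
model_label <- function(spec) {
  fe <- spec$fixed_effect %||% "null"
  if (fe == "class_x_year") fe <- "class_x_year"
  if (spec$random_individual) paste0(ifelse(fe == "null", "ind", paste0(fe, "+ind")))
  else fe
}

# sum-to-zero effect rows for a factor with L levels from free (L-1) x (K-1)
.expand_effects <- function(B) {
  rbind(B, -colSums(B))
}

# ---- MCMC ------------------------------------------------------------------

# log prior of the global ILR vector under Dirichlet(alpha) on proportions
# (includes the ILR Jacobian sum(log p); constants dropped)
.lp_global <- function(g, alpha, K) {
  p <- ilr_inverse(g, K)
  sum(alpha * log(p))
}

#' Fit the mixing model by MCMC
#'
#' Consumer-level ILR coordinates are
#' `z_i = g + effect(fixed)_i + u_i`, with sum-to-zero-coded fixed effects,
#' optional individual random effects `u_i ~ Normal(0, sigma_ind)`, a
#' Dirichlet prior on the global proportions `ilr_inverse(g)`, Normal priors
#' on fixed-effect offsets, half-Normal on `sigma_ind` and half-Cauchy(0,1)
#' on the error multipliers `xi_j`. Sampling is blockwise adaptive
#' random-walk Metropolis (one block per parameter group, per-consumer
#' vectorized accept/reject for the random effects), with step sizes adapted
#' during warmup only.
#'
#' Convergence is summarized by split R-hat over the monitored scalars
#' (global proportions, `sigma_ind`, `xi`); `converged` is `TRUE` when all
#' are below 1.05. A non-converged fit is returned with `converged = FALSE`,
#' never silently accepted.
#'
#' @param spec `mixing_model_spec`.
#' @param consumers `iso_samples` of consumers (needs `class`/`year` columns
#'   when the spec uses them).
#' @param chains number of chains (>= 3 recommended; >= 2 required).
#' @param iterations total iterations per chain (including warmup).
#' @param warmup warmup iterations discarded and used for adaptation.
#' @param seed RNG seed.
#' @param polygon_check if `TRUE`, run [mixing_polygon_check()] first and
#'   warn about consumers outside the simulated mixing polygon; `FALSE`
#'   explicitly skips the goodness-of-fit screen.
#' @return list of class `mix_fit`: `p` (draws x consumers x K), `global_p`
#'   (draws x K), `random_sd`, `error_mult` (draws x 2), `loglik_pointwise`
#'   (draws x consumers), `rhat`, `converged`, `chains`, `spec`,
#'   `consumer_id`.
#' @export
fit_mixing_model <- function(spec, consumers, chains = 3, iterations = 2000,
                             warmup = floor(iterations / 2), seed = 1,
                             polygon_check = FALSE) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  if (chains < 2) stop("need at least 2 chains", call. = FALSE)
  if (iterations - warmup < 10) stop("too few post-warmup iterations", call. = FALSE)
  K <- spec$K
  y <- cbind(consumers$d13c, consumers$d15n)
  n <- nrow(y)
  m <- .source_mats(spec$sources)
  tdf <- spec$tdf

  if (polygon_check) {
    incl <- mixing_polygon_check(consumers, spec$sources, tdf, n_iter = 500,
                                 seed = seed)
    if (any(incl < 0.05)) {
      warning(sum(incl < 0.05), " consumer(s) outside the simulated mixing ",
              "polygon (inclusion < 0.05)", call. = FALSE)
    }
  }

  # factor structure
  facs <- list()
  fe <- spec$fixed_effect
  if (!is.null(fe)) {
    want <- if (fe == "class_x_year") c("class", "year") else fe
    for (v in want) {
      if (!v %in% names(consumers)) {
        stop("design error: consumers lack covariate '", v, "'", call. = FALSE)
      }
      f <- factor(consumers[[v]])
      if (nlevels(f) < 2) stop("covariate '", v, "' has < 2 levels", call. = FALSE)
      facs[[v]] <- f
    }
  }
  n_coord <- K - 1
  use_xi <- spec$error_structure == "residual_x_process"
  use_u <- spec$random_individual

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    g <- ilr_transform(as.numeric(.rdirichlet(1, spec$prior_alpha)))
    B <- lapply(facs, function(f) matrix(stats::rnorm((nlevels(f) - 1) * n_coord, 0, 0.1),
                                         nlevels(f) - 1, n_coord))
    u <- if (use_u) matrix(stats::rnorm(n * n_coord, 0, 0.1), n, n_coord) else NULL
    log_sigma <- log(0.5)
    log_xi <- c(0, 0)

    zmat <- function(g, B, u) {
      Z <- matrix(g, n, n_coord, byrow = TRUE)
      for (v in names(facs)) {
        eff <- .expand_effects(B[[v]])
        Z <- Z + eff[as.integer(facs[[v]]), , drop = FALSE]
      }
      if (use_u) Z <- Z + u
      Z
    }
    lp_fixed <- function(B) {
      if (!length(B)) return(0)
      sum(vapply(B, function(b) sum(stats::dnorm(b, 0, spec$prior_sd_fixed, log = TRUE)),
                 numeric(1)))
    }
    lp_sigma <- function(log_sigma) {
      s <- exp(log_sigma)
      -s^2 / (2 * spec$prior_sd_sigma^2) + log_sigma  # half-Normal + Jacobian
    }
    lp_xi <- function(log_xi) {
      xi <- exp(log_xi)
      sum(-log1p(xi^2) + log_xi)  # half-Cauchy(0,1) + Jacobian
    }

    xi <- exp(log_xi); if (!use_xi) xi <- c(1, 1)
    ll <- .loglik_rows(zmat(g, B, u), y, m, tdf, xi, K)

    # joint adaptive-covariance (Haario-type) update over the non-hierarchical
    # parameters; the empirical covariance is learned in warmup and frozen
    flat <- function(g, B, log_xi) {
      th <- g
      for (v in names(facs)) th <- c(th, as.numeric(B[[v]]))
      if (use_xi) th <- c(th, log_xi)
      th
    }
    unflat <- function(th) {
      at <- n_coord
      gg <- th[seq_len(n_coord)]
      BB <- B
      for (v in names(facs)) {
        len <- length(B[[v]])
        BB[[v]] <- matrix(th[at + seq_len(len)], nrow(B[[v]]), n_coord)
        at <- at + len
      }
      lx <- if (use_xi) th[at + 1:2] else log_xi
      list(g = gg, B = BB, log_xi = lx)
    }
    th_dim <- length(flat(g, B, log_xi))
    am_mean <- numeric(th_dim); am_cov <- diag(th_dim) * 0.01
    am_n <- 0
    am_chol <- NULL
    lp_all <- function(g, B, log_xi) {
      .lp_global(g, spec$prior_alpha, K) + lp_fixed(B) +
        (if (use_xi) lp_xi(log_xi) else 0)
    }

    # adaptive step sizes per block
    steps <- list(g = 0.2, sigma = 0.3, xi = 0.3, u = 0.4)
    for (v in names(facs)) {
      steps[[paste0("B_", v)]] <- 0.2
      steps[[paste0("cell_", v)]] <- 0.3
    }
    acc <- lapply(steps, function(x) c(0, 0))  # accepted, proposed

    keep <- iterations - warmup
    out_p <- array(NA_real_, c(keep, n, K))
    out_gp <- matrix(NA_real_, keep, K)
    out_sd <- if (use_u) numeric(keep) else NULL
    out_xi <- matrix(1, keep, 2)
    out_ll <- matrix(NA_real_, keep, n)

    for (it in seq_len(iterations)) {
      # occasional large warmup jumps help chains escape poor modes; the
      # post-warmup kernel is untouched
      boost <- if (it <= warmup && it %% 25 == 0) 5 else 1
      # global ILR block
      g_new <- g + stats::rnorm(n_coord, 0, boost * steps$g)
      ll_new <- .loglik_rows(zmat(g_new, B, u), y, m, tdf, xi, K)
      lr <- sum(ll_new) - sum(ll) +
        .lp_global(g_new, spec$prior_alpha, K) - .lp_global(g, spec$prior_alpha, K)
      acc$g[2] <- acc$g[2] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        g <- g_new; ll <- ll_new; acc$g[1] <- acc$g[1] + 1
      }
      # fixed-effect blocks
      for (v in names(facs)) {
        bn <- paste0("B_", v)
        B_new <- B
        B_new[[v]] <- B[[v]] + matrix(stats::rnorm(length(B[[v]]), 0, boost * steps[[bn]]),
                                      nrow(B[[v]]), n_coord)
        ll_new <- .loglik_rows(zmat(g, B_new, u), y, m, tdf, xi, K)
        lr <- sum(ll_new) - sum(ll) + lp_fixed(B_new) - lp_fixed(B)
        acc[[bn]][2] <- acc[[bn]][2] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          B <- B_new; ll <- ll_new; acc[[bn]][1] <- acc[[bn]][1] + 1
        }
        # cell move: shift one level's total ILR (g and offsets jointly);
        # the per-level cell means are the identified quantities, so this
        # mixes far better than separate g/offset updates
        cn <- paste0("cell_", v)
        L <- nlevels(facs[[v]])
        l <- sample.int(L, 1)
        delta <- stats::rnorm(n_coord, 0, steps[[cn]])
        g_new <- g + delta / L
        B_new <- B
        if (L > 1) {
          adj <- matrix(rep(-delta / L, L - 1), L - 1, n_coord, byrow = TRUE)
          if (l < L) adj[l, ] <- delta * (L - 1) / L
          B_new[[v]] <- B[[v]] + adj
        }
        ll_new <- .loglik_rows(zmat(g_new, B_new, u), y, m, tdf, xi, K)
        lr <- sum(ll_new) - sum(ll) +
          .lp_global(g_new, spec$prior_alpha, K) - .lp_global(g, spec$prior_alpha, K) +
          lp_fixed(B_new) - lp_fixed(B)
        acc[[cn]][2] <- acc[[cn]][2] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          g <- g_new; B <- B_new; ll <- ll_new; acc[[cn]][1] <- acc[[cn]][1] + 1
        }
      }
      # individual random effects: independent per-consumer accept/reject
      if (use_u) {
        sigma <- exp(log_sigma)
        u_new <- u + matrix(stats::rnorm(n * n_coord, 0, steps$u), n, n_coord)
        ll_new <- .loglik_rows(zmat(g, B, u_new), y, m, tdf, xi, K)
        dprior <- rowSums(stats::dnorm(u_new, 0, sigma, log = TRUE)) -
          rowSums(stats::dnorm(u, 0, sigma, log = TRUE))
        lr_i <- ll_new - ll + dprior
        take <- log(stats::runif(n)) < lr_i & is.finite(lr_i)
        u[take, ] <- u_new[take, ]
        ll[take] <- ll_new[take]
        acc$u[2] <- acc$u[2] + 1
        acc$u[1] <- acc$u[1] + mean(take)
        # sigma_ind: likelihood-free given u (prior term only)
        ls_new <- log_sigma + stats::rnorm(1, 0, steps$sigma)
        lr <- sum(stats::dnorm(u, 0, exp(ls_new), log = TRUE)) -
          sum(stats::dnorm(u, 0, exp(log_sigma), log = TRUE)) +
          lp_sigma(ls_new) - lp_sigma(log_sigma)
        acc$sigma[2] <- acc$sigma[2] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          log_sigma <- ls_new; acc$sigma[1] <- acc$sigma[1] + 1
        }
      }
      # error multipliers
      if (use_xi) {
        lx_new <- log_xi + stats::rnorm(2, 0, steps$xi)
        xi_new <- exp(lx_new)
        ll_new <- .loglik_rows(zmat(g, B, u), y, m, tdf, xi_new, K)
        lr <- sum(ll_new) - sum(ll) + lp_xi(lx_new) - lp_xi(log_xi)
        acc$xi[2] <- acc$xi[2] + 1
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          log_xi <- lx_new; xi <- xi_new; ll <- ll_new
          acc$xi[1] <- acc$xi[1] + 1
        }
      }
      # joint adaptive-covariance move over (g, offsets, log xi)
      if (th_dim >= 2) {
        th <- flat(g, B, log_xi)
        if (it <= warmup) {
          if (it == floor(warmup / 2)) {  # discard early-warmup exploration
            am_mean <- numeric(th_dim); am_cov <- diag(th_dim) * 0.01; am_n <- 0
          }
          am_n <- am_n + 1
          dlt <- th - am_mean
          am_mean <- am_mean + dlt / am_n
          am_cov <- am_cov + (tcrossprod(dlt, th - am_mean) - am_cov) / am_n
          if (it == warmup) {
            am_chol <- tryCatch(chol(am_cov + diag(1e-8, th_dim)),
                                error = function(e) NULL)
          }
        }
        prop_chol <- if (it > warmup) am_chol else if (am_n > 5 * th_dim) {
          tryCatch(chol(am_cov + diag(1e-8, th_dim)), error = function(e) NULL)
        } else NULL
        if (!is.null(prop_chol)) {
          th_new <- th + drop(crossprod(prop_chol, stats::rnorm(th_dim))) *
            2.38 / sqrt(th_dim)
          st <- unflat(th_new)
          xi_new <- if (use_xi) exp(st$log_xi) else xi
          ll_new <- .loglik_rows(zmat(st$g, st$B, u), y, m, tdf, xi_new, K)
          lr <- sum(ll_new) - sum(ll) +
            lp_all(st$g, st$B, st$log_xi) - lp_all(g, B, log_xi)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            g <- st$g; B <- st$B
            if (use_xi) { log_xi <- st$log_xi; xi <- xi_new }
            ll <- ll_new
          }
        }
      }
      # step-size adaptation during warmup
      if (it <= warmup && it %% 50 == 0) {
        for (bn in names(steps)) {
          if (acc[[bn]][2] > 0) {
            rate <- acc[[bn]][1] / acc[[bn]][2]
            steps[[bn]] <- steps[[bn]] * exp(0.8 * (rate - 0.28))
            acc[[bn]] <- c(0, 0)
          }
        }
      }
      if (it > warmup) {
        k <- it - warmup
        Z <- zmat(g, B, u)
        P <- .ilr_inverse_mat(Z, K)
        out_p[k, , ] <- P
        out_gp[k, ] <- ilr_inverse(g, K)
        if (use_u) out_sd[k] <- exp(log_sigma)
        if (use_xi) out_xi[k, ] <- xi
        out_ll[k, ] <- ll
      }
    }
    list(p = out_p, gp = out_gp, sd = out_sd, xi = out_xi, ll = out_ll)
  }

  set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, chains)
  res <- lapply(chain_seeds, run_chain)

  keep <- iterations - warmup
  # split R-hat on monitored scalars, per chain
  mon <- list()
  for (k in seq_len(K)) {
    mon[[paste0("p_global[", k, "]")]] <-
      t(vapply(res, function(r) r$gp[, k], numeric(keep)))
  }
  if (use_u) mon[["sigma_ind"]] <- t(vapply(res, function(r) r$sd, numeric(keep)))
  if (use_xi) {
    mon[["xi[1]"]] <- t(vapply(res, function(r) r$xi[, 1], numeric(keep)))
    mon[["xi[2]"]] <- t(vapply(res, function(r) r$xi[, 2], numeric(keep)))
  }
  rh <- vapply(mon, rhat, numeric(1))
  converged <- all(is.finite(rh) & rh < 1.05)
  if (!converged) {
    warning("convergence flag FALSE: max split R-hat = ",
            round(max(rh, na.rm = TRUE), 3), call. = FALSE)
  }

  p_all <- do.call(abind1, lapply(res, `[[`, "p"))
  structure(list(
    p = p_all,
    global_p = do.call(rbind, lapply(res, `[[`, "gp")),
    random_sd = if (use_u) unlist(lapply(res, `[[`, "sd")) else NULL,
    error_mult = do.call(rbind, lapply(res, `[[`, "xi")),
    loglik_pointwise = do.call(rbind, lapply(res, `[[`, "ll")),
    chains = chains, rhat = rh, converged = converged,
    spec = spec, consumer_id = as.character(consumers$sample_id),
    consumer_meta = as.data.frame(consumers)[, intersect(c("sample_id", "class", "period", "year"),
                                                         names(consumers)), drop = FALSE]
  ), class = "mix_fit")
}

# bind 3-d arrays along the first margin (draws)
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], 0L)), d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# Dirichlet sampler (gamma representation)
.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  x / rowSums(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic Gelman-Rubin diagnostic computed after splitting each chain in
#' half, so within-chain trends inflate the statistic.
#'
#' @param chains_draws chains x iterations matrix.
#' @return scalar R-hat; `NaN` with a warning when within-chain variance is 0.
#' @export
rhat <- function(chains_draws) {
  x <- as.matrix(chains_draws)
  if (nrow(x) < 2 || ncol(x) < 4) stop("need >= 2 chains and >= 4 iterations", call. = FALSE)
  half <- floor(ncol(x) / 2)
  splits <- rbind(x[, seq_len(half), drop = FALSE],
                  x[, ncol(x) - half + seq_len(half), drop = FALSE])
  m <- nrow(splits); nn <- ncol(splits)
  means <- rowMeans(splits)
  W <- mean(apply(splits, 1, stats::var))
  if (!is.finite(W) || W == 0) {
    warning("zero within-chain variance: R-hat undefined", call. = FALSE)
    return(NaN)
  }
  B <- nn * stats::var(means)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# ---- mixing polygon goodness-of-fit ---------------------------------------

# even-odd ray casting; boundary tolerance via eps
.point_in_poly <- function(pt, poly, eps = 1e-12) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xcross <- (xj - xi) * (pt[2] - yi) / (yj - yi) + xi
      if (pt[1] < xcross + eps) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Simulated mixing-polygon goodness-of-fit check
#'
#' Iteratively draws each TDF-shifted source vertex from its normal
#' distribution, forms the convex hull, and records the fraction of
#' iterations in which each consumer falls inside the hull. Consumers with
#' inclusion probability below 0.05 cannot plausibly be produced by any diet
#' mixture and are flagged. With K = 2 the hull degenerates to a segment and
#' inclusion uses a perpendicular tolerance band of one pooled process SD.
#'
#' @param consumers `iso_samples` (or 2-column tracer matrix).
#' @param sources `source_summary`.
#' @param tdf `tdf_spec`.
#' @param n_iter polygon draws (warning below 100).
#' @param seed RNG seed.
#' @return named vector of per-consumer inclusion probabilities.
#' @export
mixing_polygon_check <- function(consumers, sources, tdf, n_iter = 1000, seed = 1) {
  if (n_iter < 100) warning("n_iter < 100: inclusion probabilities are coarse", call. = FALSE)
  y <- if (is.matrix(consumers)) consumers else cbind(consumers$d13c, consumers$d15n)
  ids <- if (is.matrix(consumers)) rownames(consumers) %||% as.character(seq_len(nrow(y)))
         else as.character(consumers$sample_id)
  m <- .source_mats(sources)
  K <- nrow(m$mu)
  vm <- sweep(m$mu, 2, tdf$mean, "+")
  vs <- sqrt(sweep(m$sd^2, 2, tdf$sd^2, "+"))
  set.seed(seed)
  counts <- numeric(nrow(y))
  band <- mean(vs)
  for (b in seq_len(n_iter)) {
    V <- vm + matrix(stats::rnorm(K * 2), K, 2) * vs
    if (K >= 3) {
      h <- grDevices::chull(V)
      poly <- V[h, , drop = FALSE]
      inside <- vapply(seq_len(nrow(y)),
                       function(i) .point_in_poly(y[i, ], poly), logical(1))
    } else {
      a <- V[1, ]; bb <- V[2, ]
      ab <- bb - a
      tpar <- ((y[, 1] - a[1]) * ab[1] + (y[, 2] - a[2]) * ab[2]) / sum(ab^2)
      proj <- cbind(a[1] + tpar * ab[1], a[2] + tpar * ab[2])
      perp <- sqrt(rowSums((y - proj)^2))
      inside <- tpar >= 0 & tpar <= 1 & perp <= band
    }
    counts <- counts + inside
  }
  stats::setNames(counts / n_iter, ids)
}

#' Prior versus posterior diet summaries
#'
#' Per source, the marginal prior under Dirichlet(alpha) is
#' Beta(alpha_k, alpha_0 - alpha_k); this is compared with the posterior of
#' the global proportion, reporting means, 95% intervals and an overlap
#' coefficient (integrated minimum of the two densities, grid approximation).
#'
#' @param fit `mix_fit`.
#' @return data frame with one row per source: prior/posterior mean, 2.5% and
#'   97.5% quantiles, `overlap`.
#' @export
prior_posterior_compare <- function(fit) {
  spec <- fit$spec
  alpha <- spec$prior_alpha
  a0 <- sum(alpha)
  K <- spec$K
  grid <- seq(1e-4, 1 - 1e-4, length.out = 512)
  rows <- lapply(seq_len(K), function(k) {
    draws <- fit$global_p[, k]
    prior_d <- stats::dbeta(grid, alpha[k], a0 - alpha[k])
    post_d <- tryCatch({
      dd <- stats::density(draws, from = 0, to = 1, n = 512)
      stats::approx(dd$x, dd$y, xout = grid, rule = 2)$y
    }, error = function(e) rep(NA_real_, length(grid)))
    ov <- sum(pmin(prior_d, post_d)) * (grid[2] - grid[1])
    data.frame(source = spec$sources$group[k],
               prior_mean = alpha[k] / a0,
               prior_lo = stats::qbeta(0.025, alpha[k], a0 - alpha[k]),
               prior_hi = stats::qbeta(0.975, alpha[k], a0 - alpha[k]),
               post_mean = mean(draws),
               post_lo = unname(stats::quantile(draws, 0.025)),
               post_hi = unname(stats::quantile(draws, 0.975)),
               overlap = ov)
  })
  do.call(rbind, rows)
}
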