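# Permutation multivariate statistics used for prey-group differentiation and
# diet comparisons: PERMANOVA (single- and multi-factor with marginal SS),
# pairwise contrasts with Benjamini-Yekutieli adjustment, dispersion-based
# outlier screening, and a bivariate-normality check. All permutation
# machinery is implemented here; no external ordination package is used.

#' Pairwise distance matrix for tracer data
#'
#' @param points numeric matrix (rows = samples, columns = tracers).
#' @param metric `"manhattan"` or `"euclidean"`.
#' @param labels optional row ids.
#' @return list of class `dist_matrix` with `d` (symmetric matrix), `labels`,
#'   `metric`.
#' @export
distance_matrix <- function(points, metric = c("manhattan", "euclidean"),
                            labels = NULL) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(points))) stop("missing or non-finite tracer values", call. = FALSE)
  d <- as.matrix(stats::dist(points, method = metric))
  if (is.null(labels)) labels <- rownames(points)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(points)))
  dimnames(d) <- list(labels, labels)
  structure(list(d = d, labels = labels, metric = metric), class = "dist_matrix")
}

.as_dist_matrix <- function(d) {
  if (inherits(d, "dist_matrix")) return(d)
  if (is.matrix(d)) {
    return(structure(list(d = d, labels = rownames(d) %||% as.character(seq_len(nrow(d))),
                          metric = "euclidean"), class = "dist_matrix"))
  }
  stop("expected a dist_matrix or matrix", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pseudo-F for a single grouping on squared distances.
# SS_total = sum_{i<j} d2 / n ; SS_within = sum_g (within-pair d2)/n_g
.permanova_F <- function(d2, f) {
  n <- nrow(d2)
  lev <- unique(f)
  g <- length(lev)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (l in lev) {
    idx <- which(f == l)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssb <- sst - ssw
  list(F = (ssb / (g - 1)) / (ssw / (n - g)), ss_between = ssb, ss_within = ssw,
       ss_total = sst, df1 = g - 1, df2 = n - g)
}

# all distinct relabelings of a label multiset (for exact tests, small n)
.all_relabelings <- function(f) {
  n <- length(f)
  lev <- sort(unique(f))
  counts <- table(factor(f, levels = lev))
  out <- list()
  rec <- function(remaining_idx, li, acc) {
    if (li == length(lev)) {
      lab <- acc
      lab[remaining_idx] <- lev[li]
      out[[length(out) + 1]] <<- lab
      return(invisible())
    }
    cmb <- utils::combn(remaining_idx, counts[[li]], simplify = FALSE)
    for (sel in cmb) {
      acc2 <- acc
      acc2[sel] <- lev[li]
      rec(setdiff(remaining_idx, sel), li + 1, acc2)
    }
  }
  rec(seq_len(n), 1, rep(NA_character_, n))
  out
}

#' Permutational multivariate analysis of variance
#'
#' Single-factor designs partition squared distances directly (Gower
#' identity) and permute raw group labels; multi-factor designs use marginal
#' ("partial", Type-III-like) sums of squares from hat-matrix projections of
#' the Gower-centered matrix, with permutation of residuals under the reduced
#' model. The p-value uses the add-one rule
#' `p = (1 + #permuted F >= observed F) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`.
#'
#' @param d `dist_matrix` (or plain symmetric matrix).
#' @param groups single grouping vector, or a data frame of factors for a
#'   multi-factor design.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed (permutations are reproducible given the seed).
#' @param exact if `TRUE` (single-factor only), enumerate all distinct
#'   relabelings instead of sampling; automatic for n <= 7.
#' @return list of class `permanova_result`: `table` (term, df, SS, F, R2, p),
#'   `n_perm`, `method`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1, exact = NULL) {
  d <- .as_dist_matrix(d)
  if (is.data.frame(groups) && ncol(groups) > 1) {
    return(.permanova_margin(d, groups, n_perm = n_perm, seed = seed))
  }
  if (is.data.frame(groups)) groups <- groups[[1]]
  f <- as.character(groups)
  n <- length(f)
  stopifnot(nrow(d$d) == n)
  if (length(unique(f)) < 2) stop("design error: need at least 2 groups", call. = FALSE)
  if (any(table(f) < 2)) stop("design error: every group needs >= 2 members", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  d2 <- d$d^2
  obs <- .permanova_F(d2, f)
  if (!is.finite(obs$F)) {
    warning("degenerate distances: pseudo-F undefined", call. = FALSE)
    tab <- data.frame(term = "groups", df = obs$df1, ss = obs$ss_between,
                      F = NA_real_, R2 = NA_real_, p = NA_real_)
    return(structure(list(table = tab, n_perm = 0, method = "none"),
                     class = "permanova_result"))
  }
  if (is.null(exact)) exact <- n <= 7
  if (exact) {
    labs <- .all_relabelings(f)
    fs <- vapply(labs, function(l) .permanova_F(d2, l)$F, numeric(1))
    # enumeration includes the observed labelling itself
    p <- mean(fs >= obs$F - 1e-12)
    n_used <- length(labs)
    method <- "exact"
  } else {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      fp <- f[sample.int(n)]
      if (.permanova_F(d2, fp)$F >= obs$F - 1e-12) ge <- ge + 1L
    }
    p <- (1 + ge) / (n_perm + 1)
    n_used <- n_perm
    method <- "raw permutation"
  }
  tab <- data.frame(term = "groups", df = obs$df1, ss = obs$ss_between,
                    F = obs$F, R2 = obs$ss_between / obs$ss_total, p = p)
  structure(list(table = tab, n_perm = n_used, method = method,
                 ss_total = obs$ss_total,
                 partial_ss = stats::setNames(obs$ss_between, "groups")),
            class = "permanova_result")
}

# marginal-SS multi-factor PERMANOVA (Freedman-Lane residual permutation)
.permanova_margin <- function(d, groups, n_perm, seed) {
  stopifnot(is.data.frame(groups))
  n <- nrow(d$d)
  A <- -0.5 * d$d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  terms <- names(groups)
  for (t in terms) groups[[t]] <- factor(groups[[t]])
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    Q %*% t(Q)
  }
  X_full <- stats::model.matrix(~ ., data = groups)
  H_full <- hat(X_full)
  df_res <- n - qr(X_full)$rank
  ss_res <- sum(diag(G)) - sum(diag(H_full %*% G))
  set.seed(seed)
  rows <- lapply(terms, function(t) {
    X_red <- stats::model.matrix(stats::reformulate(setdiff(terms, t) %||% "1"),
                                 data = groups)
    if (length(setdiff(terms, t)) == 0) X_red <- matrix(1, n, 1)
    H_red <- hat(X_red)
    df_t <- qr(X_full)$rank - qr(X_red)$rank
    ss_t <- sum(diag((H_full - H_red) %*% G))
    F_obs <- (ss_t / df_t) / (ss_res / df_res)
    R_red <- diag(n) - H_red
    E <- R_red %*% G %*% R_red
    ge <- 0L
    for (b in seq_len(n_perm)) {
      pi <- sample.int(n)
      Ep <- E[pi, pi]
      ss_tp <- sum(diag((H_full - H_red) %*% Ep))
      ss_rp <- sum(diag(Ep)) - sum(diag(H_full %*% Ep))
      Fp <- (ss_tp / df_t) / (ss_rp / df_res)
      if (Fp >= F_obs - 1e-12) ge <- ge + 1L
    }
    data.frame(term = t, df = df_t, ss = ss_t, F = F_obs,
               R2 = ss_t / sum(diag(G)), p = (1 + ge) / (n_perm + 1))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, n_perm = n_perm, method = "residual permutation (marginal SS)",
                 ss_total = sum(diag(G)),
                 partial_ss = stats::setNames(tab$ss, tab$term)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (", x$method, ", ", x$n_perm, " permutations)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' `adj_i = min over j >= i of c(m) * m * p_(j) / j`, with
#' `c(m) = sum_{k=1..m} 1/k`, capped at 1. Valid under arbitrary dependence
#' of the tests.
#'
#' @param p raw p-values.
#' @return adjusted p-values in the input order.
#' @export
adjust_by <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(cm * m / (m:1) * p[o]))[ro]
  adj
}

#' Pairwise PERMANOVA contrasts
#'
#' Runs a single-factor PERMANOVA on every unordered pair of groups (on the
#' corresponding distance sub-matrix) and adjusts the raw p-values with the
#' Benjamini-Yekutieli method.
#'
#' @inheritParams permanova
#' @return data frame: `group1, group2, F, p, p_adj`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 9999, seed = 1) {
  d <- .as_dist_matrix(d)
  f <- as.character(groups)
  lev <- sort(unique(f))
  if (length(lev) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    idx <- which(f %in% pr)
    sub <- structure(list(d = d$d[idx, idx, drop = FALSE],
                          labels = d$labels[idx], metric = d$metric),
                     class = "dist_matrix")
    res <- permanova(sub, f[idx], n_perm = n_perm, seed = seed + k, exact = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               F = res$table$F, p = res$table$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_by(out$p)
  out
}

#' Dispersion-based outlier screen
#'
#' Flags samples whose Euclidean distance to their group centroid (in the
#' original tracer space) exceeds `median + k * IQR` of the within-group
#' centroid distances.
#'
#' @param points tracer matrix (rows = samples).
#' @param groups grouping vector.
#' @param k threshold multiplier (default 1.5, the usual boxplot convention).
#' @param labels optional sample ids.
#' @return character vector of flagged ids.
#' @export
dispersion_outliers <- function(points, groups, k = 1.5, labels = NULL) {
  points <- as.matrix(points)
  f <- as.character(groups)
  if (is.null(labels)) labels <- rownames(points) %||% as.character(seq_len(nrow(points)))
  flagged <- character(0)
  for (g in unique(f)) {
    idx <- which(f == g)
    if (length(idx) < 3) {
      warning("group '", g, "' has < 3 members; skipped", call. = FALSE)
      next
    }
    ctr <- colMeans(points[idx, , drop = FALSE])
    dd <- sqrt(rowSums(sweep(points[idx, , drop = FALSE], 2, ctr)^2))
    thr <- stats::median(dd) + k * stats::IQR(dd)
    flagged <- c(flagged, labels[idx][dd > thr & dd > 0])
  }
  sort(flagged)
}

#' Mardia's bivariate normality test
#'
#' Multivariate skewness and kurtosis statistics with their asymptotic
#' chi-squared / normal reference distributions. Used as a warning-only
#' check of the mixing model's bivariate-normality assumption for each prey
#' group.
#'
#' @param x numeric matrix (rows = samples, columns = variables).
#' @return list with `b1` (skewness), `b2` (kurtosis), `p_skew`, `p_kurt`.
#' @export
mardia_test <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < p + 2) stop("too few observations", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n
  Sinv <- solve(S)
  D <- xc %*% Sinv %*% t(xc)
  b1 <- sum(D^3) / n^2
  b2 <- mean(diag(D)^2)
  df_skew <- p * (p + 1) * (p + 2) / 6
  stat_skew <- n * b1 / 6
  p_skew <- stats::pchisq(stat_skew, df_skew, lower.tail = FALSE)
  z_kurt <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  p_kurt <- 2 * stats::pnorm(-abs(z_kurt))
  list(b1 = b1, b2 = b2, p_skew = p_skew, p_kurt = p_kurt)
}
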