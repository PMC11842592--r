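# Post-hoc diet analyses on posterior diet estimates: individual
# specialization index (epsilon), aggregation of pelagic sources across
# areas, inter-individual heterogeneity as distance to the class centroid
# (PERMDISP-style), and diet-difference permutation tests.

#' Extract per-consumer diet estimates from a fit
#'
#' @param fit `mix_fit`.
#' @param level credible-interval level (default 0.95).
#' @return object of class `diet_estimates`: `table` (one row per consumer
#'   with posterior mean and interval per source), `draws`
#'   (draws x consumers x K), `sources`.
#' @export
diet_estimates <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mix_fit"))
  K <- fit$spec$K
  src <- fit$spec$sources$group
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  n <- length(fit$consumer_id)
  mean_p <- t(vapply(seq_len(n), function(i) colMeans(fit$p[, i, , drop = FALSE][, 1, ]),
                     numeric(K)))
  lo <- t(vapply(seq_len(n), function(i)
    apply(fit$p[, i, ], 2, stats::quantile, probs = qs[1]), numeric(K)))
  hi <- t(vapply(seq_len(n), function(i)
    apply(fit$p[, i, ], 2, stats::quantile, probs = qs[2]), numeric(K)))
  colnames(mean_p) <- src
  tab <- cbind(fit$consumer_meta,
               stats::setNames(as.data.frame(mean_p), paste0("mean_", src)),
               stats::setNames(as.data.frame(lo), paste0("lo_", src)),
               stats::setNames(as.data.frame(hi), paste0("hi_", src)))
  rownames(tab) <- NULL
  structure(list(table = tab, draws = fit$p, sources = src,
                 mean_p = mean_p), class = "diet_estimates")
}

#' Merge sources in a set of diet estimates
#'
#' Sums proportions of sources that share a merged label (e.g., combining
#' pelagic prey from different areas before computing the specialization
#' index). When posterior draws are present the merge is applied per draw,
#' so intervals remain exact.
#'
#' @param est `diet_estimates`.
#' @param merge_map named character vector mapping every source label to its
#'   merged label (identity entries allowed).
#' @param level credible-interval level for the recomputed table.
#' @return `diet_estimates` over the merged sources.
#' @export
combine_sources <- function(est, merge_map, level = 0.95) {
  stopifnot(inherits(est, "diet_estimates"))
  missing_src <- setdiff(est$sources, names(merge_map))
  if (length(missing_src)) {
    stop("configuration error: merge_map misses source(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  new_lab <- unname(merge_map[est$sources])
  targets <- unique(new_lab)
  Kn <- length(targets)
  n <- dim(est$draws)[2]
  S <- dim(est$draws)[1]
  draws <- array(0, c(S, n, Kn))
  for (t in seq_along(targets)) {
    idx <- which(new_lab == targets[t])
    draws[, , t] <- if (length(idx) == 1) est$draws[, , idx]
                    else apply(est$draws[, , idx, drop = FALSE], c(1, 2), sum)
  }
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  mean_p <- t(vapply(seq_len(n), function(i) colMeans(draws[, i, , drop = FALSE][, 1, ]),
                     numeric(Kn)))
  lo <- t(vapply(seq_len(n), function(i)
    apply(draws[, i, , drop = FALSE][, 1, , drop = TRUE], 2, stats::quantile, probs = qs[1]),
    numeric(Kn)))
  hi <- t(vapply(seq_len(n), function(i)
    apply(draws[, i, , drop = FALSE][, 1, , drop = TRUE], 2, stats::quantile, probs = qs[2]),
    numeric(Kn)))
  colnames(mean_p) <- targets
  meta_cols <- setdiff(names(est$table), grep("^(mean|lo|hi)_", names(est$table), value = TRUE))
  tab <- cbind(est$table[, meta_cols, drop = FALSE],
               stats::setNames(as.data.frame(mean_p), paste0("mean_", targets)),
               stats::setNames(as.data.frame(lo), paste0("lo_", targets)),
               stats::setNames(as.data.frame(hi), paste0("hi_", targets)))
  structure(list(table = tab, draws = draws, sources = targets, mean_p = mean_p),
            class = "diet_estimates")
}

#' Individual diet specialization index
#'
#' Normalized Euclidean distance of a diet composition from the uniform
#' (perfect-generalist) diet `u = (1/K, ..., 1/K)`:
#' \deqn{\varepsilon = \|p - u\|_2 / \sqrt{(K-1)/K}}
#' The denominator is the distance from `u` to any simplex vertex, so a
#' uniform diet scores 0 (ultra-generalist) and a single-prey diet scores 1
#' (ultra-specialist).
#'
#' @param p diet simplex (K >= 2).
#' @return epsilon in \[0, 1\].
#' @export
epsilon_index <- function(p) {
  K <- length(p)
  if (K < 2) stop("need K >= 2", call. = FALSE)
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6) {
    stop("p is not a simplex", call. = FALSE)
  }
  sqrt(sum((p - 1 / K)^2)) / sqrt((K - 1) / K)
}

#' Population-level specialization analysis
#'
#' Computes epsilon for every consumer from merged posterior-mean diets,
#' summarizes by class (mean, SD), and tests pairwise class differences in
#' mean epsilon by permutation of class labels (Benjamini-Yekutieli adjusted).
#'
#' @param est `diet_estimates` (one period).
#' @param merge_map optional source merge applied first (e.g. pooling pelagic
#'   areas).
#' @param n_perm label permutations for class contrasts.
#' @param seed RNG seed.
#' @param per_draw if `TRUE`, also return the posterior distribution of
#'   epsilon per consumer (epsilon of each draw).
#' @return list: `per_consumer` (consumer, class, epsilon), `class_summary`,
#'   `pairwise` (class1, class2, diff, p, p_adj), optionally `draws`.
#' @export
epsilon_population <- function(est, merge_map = NULL, n_perm = 999, seed = 1,
                               per_draw = FALSE) {
  if (!is.null(merge_map)) est <- combine_sources(est, merge_map)
  eps <- apply(est$mean_p, 1, epsilon_index)
  cls <- est$table$class %||% rep("all", length(eps))
  per_consumer <- data.frame(consumer_id = est$table$sample_id,
                             class = cls, epsilon = eps)
  class_summary <- do.call(rbind, lapply(split(eps, cls), function(e)
    data.frame(n = length(e), mean = mean(e), sd = stats::sd(e))))
  class_summary$class <- rownames(class_summary)
  rownames(class_summary) <- NULL
  pairwise <- NULL
  lev <- unique(cls)
  if (length(lev) >= 2) {
    set.seed(seed)
    prs <- utils::combn(lev, 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      e <- eps[cls %in% pr]; g <- cls[cls %in% pr]
      obs <- abs(mean(e[g == pr[1]]) - mean(e[g == pr[2]]))
      ge <- 0L
      for (b in seq_len(n_perm)) {
        gp <- sample(g)
        if (abs(mean(e[gp == pr[1]]) - mean(e[gp == pr[2]])) >= obs - 1e-12) ge <- ge + 1L
      }
      data.frame(class1 = pr[1], class2 = pr[2], diff = obs,
                 p = (1 + ge) / (n_perm + 1))
    })
    pairwise <- do.call(rbind, rows)
    pairwise$p_adj <- adjust_by(pairwise$p)
  }
  out <- list(per_consumer = per_consumer, class_summary = class_summary,
              pairwise = pairwise)
  if (per_draw) {
    S <- dim(est$draws)[1]; n <- dim(est$draws)[2]
    out$draws <- vapply(seq_len(n), function(i)
      apply(est$draws[, i, , drop = FALSE][, 1, , drop = TRUE], 1, epsilon_index),
      numeric(S))
  }
  out
}

#' Inter-individual diet heterogeneity (distance to group centroid)
#'
#' PERMDISP-style analysis: Euclidean distance of each consumer's posterior
#' mean diet from the arithmetic-mean centroid of its group, with group mean
#' dispersions compared by a permutation test on the distances (delegated to
#' [permanova()] on the univariate distance values). Classical MDS
#' coordinates of the diets are returned for plotting.
#'
#' @param est `diet_estimates`.
#' @param grouping column(s) of the estimate table defining groups (e.g.
#'   `"class"`, `c("class", "period")`, `"year"`).
#' @param n_perm permutations for the dispersion test.
#' @param seed RNG seed.
#' @param min_group groups smaller than this are excluded with a warning.
#' @return list: `distances` (consumer, group, distance), `dispersion`
#'   (per-group mean distance), `test` (`permanova_result` on distances),
#'   `mds` (n x 2 coordinates).
#' @export
heterogeneity <- function(est, grouping = "class", n_perm = 999, seed = 1,
                          min_group = 3) {
  tab <- est$table
  gl <- do.call(paste, c(tab[grouping], sep = ":"))
  P <- est$mean_p
  sizes <- table(gl)
  small <- names(sizes[sizes < min_group])
  if (length(small)) {
    warning("excluding group(s) with < ", min_group, " members: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !gl %in% small
    P <- P[keep, , drop = FALSE]; gl <- gl[keep]; tab <- tab[keep, , drop = FALSE]
  }
  if (length(unique(gl)) < 1) stop("no usable groups", call. = FALSE)
  dist_to_ctr <- numeric(nrow(P))
  for (g in unique(gl)) {
    idx <- which(gl == g)
    ctr <- colMeans(P[idx, , drop = FALSE])
    dist_to_ctr[idx] <- sqrt(rowSums(sweep(P[idx, , drop = FALSE], 2, ctr)^2))
  }
  distances <- data.frame(consumer_id = tab$sample_id, group = gl,
                          distance = dist_to_ctr)
  dispersion <- do.call(rbind, lapply(split(dist_to_ctr, gl), function(d)
    data.frame(n = length(d), mean_distance = mean(d), sd = stats::sd(d))))
  dispersion$group <- rownames(dispersion)
  rownames(dispersion) <- NULL
  test <- NULL
  if (length(unique(gl)) >= 2) {
    dd <- distance_matrix(cbind(dist_to_ctr, 0), metric = "euclidean",
                          labels = as.character(tab$sample_id))
    test <- permanova(dd, gl, n_perm = n_perm, seed = seed, exact = FALSE)
  }
  dmat <- stats::dist(P)
  mds <- tryCatch(stats::cmdscale(dmat, k = 2), error = function(e) NULL)
  list(distances = distances, dispersion = dispersion, test = test, mds = mds)
}

#' Permutation test of diet differences between groups
#'
#' PERMANOVA on the Euclidean distances between posterior mean diets, with
#' pairwise Benjamini-Yekutieli-adjusted contrasts when more than two levels
#' are present.
#'
#' @param est `diet_estimates` (or an rbind of tables from several periods via
#'   `merge_estimates`).
#' @param factor grouping column(s): `"class"`, `"period"`, or
#'   `c("class", "period")`.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: `global` (`permanova_result`), `pairwise` (or `NULL`).
#' @export
diet_difference_test <- function(est, factor = "class", n_perm = 999, seed = 1) {
  tab <- est$table
  gl <- do.call(paste, c(tab[factor], sep = ":"))
  if (length(unique(gl)) < 2) stop("need >= 2 factor levels", call. = FALSE)
  dd <- distance_matrix(est$mean_p, metric = "euclidean",
                        labels = as.character(tab$sample_id))
  global <- permanova(dd, gl, n_perm = n_perm, seed = seed, exact = FALSE)
  pw <- if (length(unique(gl)) >= 3) {
    pairwise_permanova(dd, gl, n_perm = n_perm, seed = seed)
  } else NULL
  list(global = global, pairwise = pw)
}
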