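# fixture builders shared across test files

# minimal source summary: K well-separated sources with unit concentrations
make_sources <- function(K = 3,
                         mu_c = seq(-22, -16, length.out = K),
                         mu_n = 12 + 5 * (seq_len(K) %% 2) + 0.7 * seq_len(K),
                         sd = 0.6, conc_c = 0.45, conc_n = 0.12,
                         period = "P2000s") {
  out <- data.frame(group = paste0("s", seq_len(K)), period = period, n = 10,
                    mean_d13c = mu_c, mean_d15n = mu_n,
                    sd_d13c = rep(sd, K), sd_d15n = rep(sd, K),
                    conc_c = rep(conc_c, K), conc_n = rep(conc_n, K))
  class(out) <- c("source_summary", "data.frame")
  out
}

# assemble a diet_estimates object directly from known diets (draws optional)
make_estimates <- function(mean_p, class = NULL, period = "P2000s",
                           year = 2000L, draws = NULL) {
  n <- nrow(mean_p)
  K <- ncol(mean_p)
  src <- colnames(mean_p)
  if (is.null(src)) src <- paste0("s", seq_len(K))
  colnames(mean_p) <- src
  if (is.null(class)) class <- rep("adult_male", n)
  if (is.null(draws)) {
    draws <- array(NA_real_, c(2, n, K))
    draws[1, , ] <- mean_p
    draws[2, , ] <- mean_p
  }
  tab <- data.frame(sample_id = sprintf("C%03d", seq_len(n)), class = class,
                    period = period, year = year)
  tab <- cbind(tab, stats::setNames(as.data.frame(mean_p), paste0("mean_", src)),
               stats::setNames(as.data.frame(mean_p), paste0("lo_", src)),
               stats::setNames(as.data.frame(mean_p), paste0("hi_", src)))
  structure(list(table = tab, draws = draws, sources = src, mean_p = mean_p),
            class = "diet_estimates")
}

# write a consumer/prey CSV fixture and return its path
write_fixture_csv <- function(df, name = "fixture.csv") {
  path <- file.path(tempdir(), name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

consumer_fixture_df <- function(n = 3) {
  data.frame(sample_id = sprintf("b%d", seq_len(n)),
             class = rep("adult_male", n), period = rep("P2000s", n),
             year = rep(2000L, n),
             d13c = seq(-19, -18, length.out = n),
             d15n = seq(15, 16, length.out = n))
}

prey_fixture_df <- function() {
  data.frame(sample_id = paste0("p", 1:4),
             taxon = c("capelin", "capelin", "herring", "herring"),
             group = "pelagic", region = "UE", period = "P2000s",
             year = 2000L, d13c = c(-20, -22, -20.5, -21.5),
             d15n = c(12, 13, 12.5, 13.5), pct_c = 45, pct_n = 12)
}
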