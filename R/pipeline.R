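# Config-driven orchestration: corrections -> source grouping -> per-period
# candidate-model fits -> information-criterion ranking -> diet estimates ->
# specialization -> heterogeneity, with a manifest recording seeds, file
# hashes and convergence flags. A thin command-line front end exposes the
# individual stages.

#' The standard candidate-model set
#'
#' The eight models fitted per period: no covariates (null), each fixed
#' effect alone (class, year), the individual random effect alone
#' (process-only error, the only identifiable choice there), fixed effects
#' with the individual random effect, and additive crossed class + year
#' effects with and without the random effect. All others use the
#' multiplicative (residual x process) error.
#'
#' @param sources `source_summary` for the period.
#' @param tdf `tdf_spec`.
#' @return named list of `mixing_model_spec`.
#' @export
candidate_models <- function(sources, tdf = tdf_spec()) {
  mk <- function(fe, ri) mixing_model_spec(sources, tdf, fixed_effect = fe,
                                           random_individual = ri)
  list(
    null = mk(NULL, FALSE),
    class = mk("class", FALSE),
    ind = suppressMessages(mk(NULL, TRUE)),
    year = mk("year", FALSE),
    `class+ind` = mk("class", TRUE),
    `year+ind` = mk("year", TRUE),
    class_x_year = mk("class_x_year", FALSE),
    `class_x_year+ind` = mk("class_x_year", TRUE)
  )
}

#' Run the full analysis pipeline
#'
#' @param config named list (or path to a JSON file) with entries:
#'   `scenario` (name of a built-in scenario or path to a scenario JSON) or
#'   `consumers_csv`/`prey_csv`; `models` (labels from [candidate_models()],
#'   default all eight); `mcmc` (`chains`, `iterations`, `warmup`);
#'   `suess` (`region`, `reference_year`) or `skip_corrections = TRUE`;
#'   `merge_map` (named list for epsilon source pooling); `n_perm`; `seed`;
#'   `out_dir`.
#' @return invisibly, the manifest list; all stage outputs are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  out_dir <- config$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 999L
  mcmc <- config$mcmc %||% list()
  chains <- mcmc$chains %||% 3L
  iterations <- mcmc$iterations %||% 1500L
  warmup <- mcmc$warmup %||% floor(iterations / 2)
  manifest <- list(seed = seed, stages = list(), started = format(Sys.time()))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, file) {
    manifest$stages[[name]] <<- list(
      file = file, md5 = unname(tools::md5sum(file)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sc <- if (file.exists(config$scenario)) read_scenario(config$scenario)
          else default_scenarios()[[config$scenario]]
    if (is.null(sc)) stop("unknown scenario '", config$scenario, "'", call. = FALSE)
    prey <- generate_prey(sc, seed = seed)
    gen <- generate_consumers(sc, seed = seed + 1L)
    consumers <- gen$consumers
    utils::write.csv(gen$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    tdf <- sc$tdf
  } else {
    consumers <- read_samples(config$consumers_csv, "consumer",
                              strict = isTRUE(config$strict))
    prey <- read_samples(config$prey_csv, "prey", strict = isTRUE(config$strict))
    tdf <- if (!is.null(config$tdf)) tdf_spec(config$tdf$mean, config$tdf$sd) else tdf_spec()
  }

  # -- stage 1: corrections -------------------------------------------------
  if (!isTRUE(config$skip_corrections)) {
    ref_years <- list(P2000s = 2002L, P2020s = 2020L)
    params <- lapply(ref_years, function(ry)
      load_suess_params(region = config$suess$region %||% "north_atlantic",
                        reference_year = ry))
    consumers <- apply_corrections(consumers, params)
    prey <- apply_corrections(prey, params)
  }
  f <- file.path(out_dir, "corrected_consumers.csv")
  write_samples(consumers, f); stage("corrections", f)

  # -- stage 2: source grouping --------------------------------------------
  grouping <- if (!is.null(config$grouping)) unlist(config$grouping) else NULL
  periods <- sort(unique(consumers$period))
  sources <- lapply(periods, function(p) summarize_sources(prey, grouping, p))
  names(sources) <- periods
  f <- file.path(out_dir, "sources.csv")
  utils::write.csv(do.call(rbind, sources), f, row.names = FALSE); stage("sources", f)

  # -- stage 3: model fits --------------------------------------------------
  want <- config$models %||% names(candidate_models(sources[[1]], tdf))
  fits <- list(); score_rows <- list()
  for (p in periods) {
    zoo <- candidate_models(sources[[p]], tdf)
    bad <- setdiff(want, names(zoo))
    if (length(bad)) stop("unknown model label(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cons_p <- consumers[consumers$period == p, , drop = FALSE]
    for (mlab in want) {
      fit <- fit_mixing_model(zoo[[mlab]], cons_p, chains = chains,
                              iterations = iterations, warmup = warmup,
                              seed = seed + 100L)
      fits[[paste(p, mlab)]] <- fit
      score_rows[[paste(p, mlab)]] <- score_model(fit, mlab, p)
    }
  }
  scores <- do.call(rbind, score_rows)
  f <- file.path(out_dir, "model_scores.csv")
  utils::write.csv(scores, f, row.names = FALSE); stage("fits", f)
  if (any(!scores$converged)) {
    warning("non-converged model(s) excluded from ranking: ",
            paste(scores$model[!scores$converged], collapse = ", "), call. = FALSE)
  }

  # -- stage 4: ranking -----------------------------------------------------
  usable <- if (any(scores$converged)) scores[scores$converged, , drop = FALSE]
            else { warning("no model converged; ranking all candidates", call. = FALSE); scores }
  ranking <- rank_models(usable)
  f <- file.path(out_dir, "model_ranking.csv")
  utils::write.csv(ranking, f, row.names = FALSE); stage("ranking", f)

  # -- stage 5: diet estimates (best model per period) ----------------------
  est_tabs <- list(); ests <- list()
  for (p in periods) {
    rp <- ranking[ranking$period == p, , drop = FALSE]
    best <- rp$model[1]
    ests[[p]] <- diet_estimates(fits[[paste(p, best)]])
    est_tabs[[p]] <- cbind(best_model = best, ests[[p]]$table)
  }
  f <- file.path(out_dir, "diet_estimates.csv")
  utils::write.csv(do.call(rbind, lapply(est_tabs, function(t) {
    t[, c("best_model", "sample_id", intersect(c("class", "period", "year"), names(t)),
          grep("^mean_", names(t), value = TRUE))]
  })), f, row.names = FALSE); stage("diet_estimates", f)

  # -- stage 6: specialization ---------------------------------------------
  merge_map <- if (!is.null(config$merge_map)) unlist(config$merge_map) else NULL
  eps_rows <- lapply(periods, function(p) {
    mm <- merge_map
    if (!is.null(mm)) mm <- mm[intersect(names(mm), ests[[p]]$sources)]
    if (!is.null(mm) && length(mm) < length(ests[[p]]$sources)) {
      ids <- setdiff(ests[[p]]$sources, names(mm))
      mm <- c(mm, stats::setNames(ids, ids))
    }
    ep <- epsilon_population(ests[[p]], merge_map = mm, n_perm = n_perm, seed = seed)
    cbind(period = p, ep$per_consumer)
  })
  f <- file.path(out_dir, "epsilon.csv")
  utils::write.csv(do.call(rbind, eps_rows), f, row.names = FALSE); stage("epsilon", f)

  # -- stage 7: heterogeneity ----------------------------------------------
  disp_rows <- lapply(periods, function(p) {
    h <- heterogeneity(ests[[p]], grouping = "class", n_perm = n_perm, seed = seed)
    cbind(period = p, h$distances)
  })
  f <- file.path(out_dir, "dispersion.csv")
  utils::write.csv(do.call(rbind, disp_rows), f, row.names = FALSE); stage("dispersion", f)

  manifest$rhat_ok <- stats::setNames(scores$converged, rownames(scores))
  manifest$finished <- format(Sys.time())
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate --scenario <name> --out <dir> [--seed N]`;
#' `correct --in <csv> --schema consumer|prey --reference-year Y --out <csv>`;
#' `group --prey <csv> --period P --out <csv>`;
#' `fit --consumers <csv> --sources <csv> --model <label> --out <csv>`
#' (posterior summary); `pipeline --config <json>`. Returns the process exit
#' code: 0 ok, 1 usage error, 2 stage failure.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit code (invisibly).
#' @export
iso_cli <- function(args) {
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) return(default)
    if (i == length(args)) stop("missing value for --", name, call. = FALSE)
    args[i + 1]
  }
  code <- tryCatch({
    if (length(args) == 0) stop("usage: isodiet <simulate|correct|group|fit|rank|pipeline> ...",
                                call. = FALSE)
    cmd <- args[1]
    seed <- as.integer(opt("seed", "1"))
    switch(cmd,
      simulate = {
        sc_name <- opt("scenario") %||% stop("--scenario required", call. = FALSE)
        out <- opt("out") %||% "."
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        sc <- default_scenarios()[[sc_name]] %||%
          (if (file.exists(sc_name)) read_scenario(sc_name) else
             stop("unknown scenario: ", sc_name, call. = FALSE))
        prey <- generate_prey(sc, seed = seed)
        gen <- generate_consumers(sc, seed = seed + 1L)
        write_samples(prey, file.path(out, "prey.csv"))
        write_samples(gen$consumers, file.path(out, "consumers.csv"))
        utils::write.csv(gen$truth, file.path(out, "truth.csv"), row.names = FALSE)
        message("wrote prey.csv, consumers.csv, truth.csv to ", out)
        0L
      },
      correct = {
        path <- opt("in") %||% stop("--in required", call. = FALSE)
        schema <- opt("schema", "consumer")
        ry <- as.integer(opt("reference-year") %||%
                           stop("--reference-year required", call. = FALSE))
        x <- read_samples(path, schema, strict = "--strict" %in% args)
        x <- apply_corrections(x, load_suess_params(reference_year = ry))
        write_samples(x, opt("out", "corrected.csv"))
        0L
      },
      group = {
        prey <- read_samples(opt("prey") %||% stop("--prey required", call. = FALSE), "prey")
        period <- opt("period") %||% stop("--period required", call. = FALSE)
        src <- summarize_sources(prey, NULL, period)
        utils::write.csv(src, opt("out", "sources.csv"), row.names = FALSE)
        0L
      },
      fit = {
        consumers <- read_samples(opt("consumers") %||% stop("--consumers required", call. = FALSE),
                                  "consumer")
        src <- utils::read.csv(opt("sources") %||% stop("--sources required", call. = FALSE))
        class(src) <- c("source_summary", "data.frame")
        zoo <- candidate_models(src)
        mlab <- opt("model", "null")
        if (!mlab %in% names(zoo)) stop("unknown model '", mlab, "'", call. = FALSE)
        fit <- fit_mixing_model(zoo[[mlab]], consumers,
                                chains = as.integer(opt("chains", "3")),
                                iterations = as.integer(opt("iters", "1500")),
                                seed = seed)
        est <- diet_estimates(fit)
        utils::write.csv(est$table, opt("out", "diet_estimates.csv"), row.names = FALSE)
        0L
      },
      pipeline = {
        run_pipeline(opt("config") %||% stop("--config required", call. = FALSE))
        0L
      },
      stop("unknown subcommand: ", cmd, call. = FALSE)
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("usage|required|unknown", conditionMessage(e))) 1L else 2L
  })
  invisible(code)
}
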