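#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> beliefs -> designs -> fits -> metrics over a
#' single JSON-style configuration, writing every stage's tables plus a
#' run manifest (seeds, per-stage timings and row counts, output paths)
#' under `out_dir`. Either simulates sessions from an agent specification
#' or loads previously written session CSVs (validated on read; e.g. a
#' partial-feedback log carrying unchosen outcomes is rejected).
#'
#' @param config A list (or path to a JSON file) with optional elements:
#'   `sessions_dir` (load instead of simulate), `task` (arguments to
#'   [task_config()]), `agent` (arguments to [agent_params()]),
#'   `observer` (arguments to [observer_config()]), `fit` (arguments to
#'   [fit_config()]), `animals`, `sessions_per_condition`, `feedback`,
#'   `variant`, `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  variant <- config$variant %||% "uncertainty"
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("horizontask")),
                   stages = list(), outputs = character())
  note <- function(stage, t0, rows, files) {
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      rows = rows)
    manifest$outputs <<- c(manifest$outputs, files)
  }

  task_cfg <- do.call(task_config, config$task %||% list())
  obs_cfg <- do.call(observer_config, config$observer %||% list())

  t0 <- Sys.time()
  if (!is.null(config$sessions_dir)) {
    sessions <- read_sessions(config$sessions_dir)
    note("load_sessions", t0, sum(vapply(sessions, function(s) nrow(s$choices), 0L)),
         character())
  } else {
    agent <- do.call(agent_params, config$agent %||% list())
    sessions <- simulate_experiment(
      agent, config = task_cfg, observer = obs_cfg,
      animals = config$animals %||% paste0("m", 1:3),
      sessions_per_condition = config$sessions_per_condition %||% 2L,
      feedback = config$feedback %||% c("partial", "complete"),
      seed = seed
    )
    ses_dir <- file.path(out_dir, "sessions")
    paths <- write_sessions(sessions, ses_dir)
    note("simulate", t0, sum(vapply(sessions, function(s) nrow(s$choices), 0L)),
         paths)
  }

  t0 <- Sys.time()
  beliefs <- do.call(rbind, lapply(sessions, session_beliefs, config = obs_cfg))
  bpath <- file.path(out_dir, "beliefs.csv")
  utils::write.csv(beliefs, bpath, row.names = FALSE)
  note("beliefs", t0, nrow(beliefs), bpath)

  t0 <- Sys.time()
  d1 <- build_first_choice_design(sessions, obs_cfg, variant = variant)
  d1_path <- file.path(out_dir, "design_first.csv")
  write_design(d1, d1_path)
  has_subsequent <- any(vapply(sessions, function(s) {
    any(s$trials$horizon == s$config$horizon_long & s$trials$trial_id %in%
          s$choices$trial_id[s$choices$choice_index >= 2L])
  }, logical(1)))
  d2 <- NULL
  files <- c(d1_path, paste0(d1_path, ".schema.json"))
  if (has_subsequent) {
    d2 <- build_subsequent_choice_design(sessions, obs_cfg)
    d2_path <- file.path(out_dir, "design_subsequent.csv")
    write_design(d2, d2_path)
    files <- c(files, d2_path, paste0(d2_path, ".schema.json"))
  }
  note("designs", t0, nrow(d1) + if (is.null(d2)) 0L else nrow(d2), files)

  fit_cfg <- do.call(fit_config, config$fit %||%
                       list(n_chains = 2L, n_warmup = 200L, n_samples = 200L))
  t0 <- Sys.time()
  fit1 <- fit_choice_model(d1, fit_cfg)
  write_fit(fit1, file.path(out_dir, "fit_first"))
  files <- file.path(out_dir, c("fit_first_draws.csv", "fit_first_summary.json"))
  fit2 <- NULL
  if (!is.null(d2)) {
    fit2 <- fit_choice_model(d2, fit_cfg)
    write_fit(fit2, file.path(out_dir, "fit_subsequent"))
    files <- c(files, file.path(out_dir, c("fit_subsequent_draws.csv",
                                           "fit_subsequent_summary.json")))
  }
  note("fits", t0, fit1$n_draws + if (is.null(fit2)) 0L else fit2$n_draws, files)

  t0 <- Sys.time()
  acc <- accuracy_table(sessions, obs_cfg)
  rep_tab <- repetition_table(sessions)
  psy <- psychometric_curve(sessions, obs_cfg)
  trend_acc <- within_horizon_trend(sessions, "accuracy", obs_cfg)
  trend_rep <- within_horizon_trend(sessions, "repetition")
  mpaths <- file.path(out_dir, c("accuracy.csv", "repetition.csv",
                                 "psychometric.csv", "metrics_tests.json"))
  utils::write.csv(acc$by_cell, mpaths[1], row.names = FALSE)
  utils::write.csv(rep_tab$by_cell, mpaths[2], row.names = FALSE)
  utils::write.csv(psy, mpaths[3], row.names = FALSE)
  jsonlite::write_json(
    list(accuracy_trend = trend_acc$ttest, accuracy_trend_dropped = trend_acc$dropped,
         repetition_trend = trend_rep$ttest,
         repetition_trend_dropped = trend_rep$dropped),
    mpaths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("metrics", t0, nrow(acc$per_session), mpaths)

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate-and-refit parameter recovery
#'
#' Simulates an experiment with known agent coefficients, fits the
#' requested choice model, and tabulates truth against the posterior per
#' coefficient and cell: posterior mean, 95% interval, interval coverage
#' of the truth and bias. Non-converged fits are recorded in the report,
#' not hidden.
#'
#' @param truth An [agent_params()] or a function
#'   `function(animal_id, feedback) -> agent_params` defining the
#'   generative coefficients per cell.
#' @param model `"first"` or `"subsequent"`: which choice model to refit.
#' @param config A [task_config()].
#' @param observer An [observer_config()].
#' @param fit_cfg A [fit_config()].
#' @param animals,sessions_per_condition,feedback Experiment scale, as in
#'   [simulate_experiment()].
#' @param seed Integer seed for simulation.
#' @return A list with `table` (truth vs posterior per coefficient x
#'   cell, group rows included as `animal = "group"`), `fit`, `flagged`
#'   and the simulated `sessions`.
#' @export
run_recovery <- function(truth,
                         model = c("first", "subsequent"),
                         config = task_config(),
                         observer = observer_config(sigma = config$outcome_sd),
                         fit_cfg = fit_config(n_chains = 2L, n_warmup = 200L,
                                              n_samples = 300L),
                         animals = paste0("m", 1:3),
                         sessions_per_condition = 4L,
                         feedback = c("partial", "complete"),
                         seed = 1L) {
  model <- match.arg(model)
  truth_fun <- if (is.function(truth)) truth else function(a, f) truth
  variant <- truth_fun(animals[1], feedback[1])$variant
  sessions <- simulate_experiment(truth_fun, config = config, observer = observer,
                                  animals = animals,
                                  sessions_per_condition = sessions_per_condition,
                                  feedback = feedback, seed = seed)
  design <- if (model == "first") {
    build_first_choice_design(sessions, observer, variant = variant)
  } else {
    build_subsequent_choice_design(sessions, observer)
  }
  fit <- fit_choice_model(design, fit_cfg)

  rows <- list()
  for (ci in seq_len(nrow(fit$cells))) {
    tp <- truth_fun(fit$cells$animal[ci], fit$cells$condition[ci])
    tv <- if (model == "first") tp$first else tp$subsequent
    for (k in seq_along(fit$coefficients)) {
      d <- fit$mu[, k, ci]
      tr_val <- tv[[fit$coefficients[k]]]
      qs <- stats::quantile(d, c(0.025, 0.975))
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = fit$coefficients[k],
        animal = fit$cells$animal[ci], condition = fit$cells$condition[ci],
        truth = tr_val, post_mean = mean(d),
        q2.5 = unname(qs[1]), q97.5 = unname(qs[2]),
        covered = tr_val >= qs[1] && tr_val <= qs[2],
        bias = mean(d) - tr_val
      )
    }
  }
  # Group-level rows: average over animals within condition, for truths that
  # are shared across animals the group truth is their mean.
  for (cond in fit$conditions) {
    truths <- vapply(fit$animals, function(a) {
      tp <- truth_fun(a, cond)
      tv <- if (model == "first") tp$first else tp$subsequent
      tv[fit$coefficients]
    }, numeric(length(fit$coefficients)))
    for (k in seq_along(fit$coefficients)) {
      d <- group_draws(fit, fit$coefficients[k], condition = cond)
      tr_val <- mean(truths[k, ])
      qs <- stats::quantile(d, c(0.025, 0.975))
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = fit$coefficients[k],
        animal = "group", condition = cond,
        truth = tr_val, post_mean = mean(d),
        q2.5 = unname(qs[1]), q97.5 = unname(qs[2]),
        covered = tr_val >= qs[1] && tr_val <= qs[2],
        bias = mean(d) - tr_val
      )
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, fit = fit, flagged = fit$flagged, sessions = sessions)
}
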