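#' Write sessions as per-session CSV logs with JSON sidecars
#'
#' One CSV per session, one row per choice, with the observation-phase
#' samples semicolon-joined; a JSON sidecar holds the task configuration
#' and seed. UTF-8, header row mandatory.
#'
#' @param sessions A `horizon_session` or list of them, with choices.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the CSV paths written.
#' @export
write_sessions <- function(sessions, dir) {
  sessions <- check_sessions(sessions)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(sessions, function(s) {
    ch <- s$choices[order(s$choices$trial_id, s$choices$choice_index), ]
    tr <- s$trials[match(ch$trial_id, s$trials$trial_id), ]
    df <- data.frame(
      session_id = s$session_id,
      animal_id = s$animal_id,
      feedback = s$feedback,
      trial_id = ch$trial_id,
      horizon = tr$horizon,
      choice_index = ch$choice_index,
      side_chosen = ifelse(ch$side == "right", "R", "L"),
      chosen_outcome = ch$chosen_outcome,
      unchosen_outcome = ch$unchosen_outcome,
      obs_left = vapply(tr$obs_left, paste, "", collapse = ";"),
      obs_right = vapply(tr$obs_right, paste, "", collapse = ";"),
      true_mean_left = tr$true_mean_left,
      true_mean_right = tr$true_mean_right
    )
    path <- file.path(dir, paste0(s$session_id, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    cfg <- s$config
    class(cfg) <- NULL
    jsonlite::write_json(list(config = cfg, seed = s$seed,
                              session_id = s$session_id,
                              animal_id = s$animal_id),
                         file.path(dir, paste0(s$session_id, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
    path
  }, character(1))
  invisible(paths)
}

#' Read session logs written by [write_sessions()]
#'
#' Validates the logs while reading: a session must hold a single feedback
#' condition and animal, partial-feedback sessions must not carry unchosen
#' outcomes, complete-feedback sessions must carry them for every choice,
#' every trial needs the configured number of informative observations
#' with at least one per side, and all outcomes must lie in the configured
#' support.
#'
#' @param dir Directory containing `<session_id>.csv` and
#'   `<session_id>.json` pairs.
#' @return A list of `horizon_session` objects.
#' @export
read_sessions <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stopf("no session CSV files found in %s", dir)
  lapply(files, read_one_session)
}

read_one_session <- function(path) {
  df <- utils::read.csv(path, colClasses = c(obs_left = "character",
                                             obs_right = "character"))
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) stopf("missing JSON sidecar for %s", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  cfg <- do.call(task_config, meta$config[setdiff(names(meta$config), NULL)])

  if (length(unique(df$feedback)) != 1L) {
    stopf("%s mixes feedback conditions within one session", path)
  }
  if (length(unique(df$animal_id)) != 1L || length(unique(df$session_id)) != 1L) {
    stopf("%s mixes session or animal identifiers", path)
  }
  feedback <- df$feedback[1]
  if (!feedback %in% c("partial", "complete")) {
    stopf("%s: unknown feedback condition `%s`", path, feedback)
  }
  if (feedback == "partial" && any(!is.na(df$unchosen_outcome))) {
    stopf("%s: partial-feedback session contains unchosen_outcome values", path)
  }
  if (feedback == "complete" && any(is.na(df$unchosen_outcome))) {
    stopf("%s: complete-feedback session is missing unchosen_outcome values", path)
  }
  cfg$feedback <- feedback

  parse_obs <- function(x) {
    if (!nzchar(x)) return(integer())
    as.integer(strsplit(x, ";", fixed = TRUE)[[1]])
  }
  tr_rows <- df[!duplicated(df$trial_id), ]
  obs_left <- lapply(tr_rows$obs_left, parse_obs)
  obs_right <- lapply(tr_rows$obs_right, parse_obs)
  n_obs <- lengths(obs_left) + lengths(obs_right)
  if (any(n_obs != cfg$n_observations)) {
    stopf("%s: trial(s) without exactly %d informative observations",
          path, cfg$n_observations)
  }
  if (any(lengths(obs_left) == 0L) || any(lengths(obs_right) == 0L)) {
    stopf("%s: every option needs at least one informative observation", path)
  }
  vals <- c(unlist(obs_left), unlist(obs_right), df$chosen_outcome,
            df$unchosen_outcome[!is.na(df$unchosen_outcome)])
  if (any(vals < cfg$outcome_min | vals > cfg$outcome_max)) {
    stopf("%s: outcome value(s) outside [%d, %d]",
          path, cfg$outcome_min, cfg$outcome_max)
  }

  trials <- data.frame(
    trial_id = tr_rows$trial_id,
    horizon = tr_rows$horizon,
    block = NA_integer_,
    equal_split = lengths(obs_left) == lengths(obs_right),
    true_mean_left = tr_rows$true_mean_left,
    true_mean_right = tr_rows$true_mean_right
  )
  trials$obs_left <- I(obs_left)
  trials$obs_right <- I(obs_right)
  choices <- data.frame(
    trial_id = df$trial_id,
    choice_index = df$choice_index,
    side = ifelse(df$side_chosen == "R", "right", "left"),
    chosen_outcome = df$chosen_outcome,
    unchosen_outcome = df$unchosen_outcome
  )
  if (any(choices$choice_index > trials$horizon[match(choices$trial_id,
                                                      trials$trial_id)])) {
    stopf("%s: more choices than the trial's horizon allows", path)
  }
  structure(
    list(session_id = df$session_id[1], animal_id = df$animal_id[1],
         feedback = feedback, config = cfg, seed = meta$seed,
         trials = trials, choices = choices),
    class = "horizon_session"
  )
}
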