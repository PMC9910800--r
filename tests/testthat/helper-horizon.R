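# Shared fixtures and independent oracles, all built in code.

# Naive direct-enumeration oracle for the ideal observer: a plain double
# loop over grid x observations, no log space. Kept deliberately
# independent of the package's log-space implementation.
oracle_belief <- function(obs, grid, sigma, support,
                          prior = rep(1 / length(grid), length(grid))) {
  lik <- matrix(NA_real_, length(support), length(grid))
  for (j in seq_along(grid)) {
    k <- exp(-(support - grid[j])^2 / (2 * sigma^2))
    lik[, j] <- k / sum(k)
  }
  post <- prior
  for (x in obs) post <- post * lik[match(x, support), ]
  post <- post / sum(post)
  pred <- as.vector(lik %*% post)
  ev <- sum(support * pred)
  list(posterior = post, predictive = pred,
       ev = ev, u = sum((support - ev)^2 * pred))
}

# Construct a horizon_session directly from trial and choice tables, for
# hand-built edge cases.
manual_session <- function(trials, choices, feedback = "partial",
                           config = task_config(trials_per_session = 10,
                                                feedback = feedback),
                           session_id = "manual", animal_id = "m1") {
  config$feedback <- feedback
  structure(
    list(session_id = session_id, animal_id = animal_id, feedback = feedback,
         config = config, seed = NA_integer_,
         trials = trials, choices = choices),
    class = "horizon_session"
  )
}

manual_trials <- function(horizon, obs_left, obs_right) {
  n <- length(horizon)
  tr <- data.frame(trial_id = seq_len(n), horizon = horizon,
                   block = NA_integer_,
                   equal_split = lengths(obs_left) == lengths(obs_right),
                   true_mean_left = 5, true_mean_right = 5)
  tr$obs_left <- I(obs_left)
  tr$obs_right <- I(obs_right)
  tr
}

# Left-right mirror of a session: swaps observation sets, true means and
# choice sides; chosen/unchosen outcomes follow the swap automatically.
mirror_session <- function(session) {
  tr <- session$trials
  tmp <- tr$obs_left; tr$obs_left <- tr$obs_right; tr$obs_right <- tmp
  tmp <- tr$true_mean_left
  tr$true_mean_left <- tr$true_mean_right
  tr$true_mean_right <- tmp
  ch <- session$choices
  ch$side <- ifelse(ch$side == "right", "left", "right")
  session$trials <- tr
  session$choices <- ch
  session$session_id <- paste0(session$session_id, "_mirror")
  session
}

# Small simulated experiment used by several tests (computed once per run).
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      oc <- observer_config()
      ag <- agent_params(
        first = c(EV = 0.8, U = -0.2, RB = 0.3, EVxhorizon = 0.2),
        subsequent = c(baselineEV = 0.6, dEVchosen = 0.6, RB = 0.4,
                       dChosen = 0.2, dEVunchosen = 0.4)
      )
      cache <<- simulate_experiment(
        ag, config = task_config(trials_per_session = 40),
        observer = oc, animals = c("m1", "m2"),
        sessions_per_condition = 2L, seed = 99L
      )
    }
    cache
  }
})
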