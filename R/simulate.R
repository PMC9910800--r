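#' Draw integer outcomes from an option's reward distribution
#'
#' Outcomes are Gaussian draws with SD `config$outcome_sd` around the
#' option's true mean, rounded half-up to the nearest integer number of
#' drops and clamped to the outcome support. `raw = TRUE` returns the
#' pre-rounding Gaussian draws (useful to check the generative SD).
#'
#' @param mean True mean of the option, in drops; must lie within the
#'   configured mean range.
#' @param config A [task_config()].
#' @param n Number of draws.
#' @param raw If `TRUE`, return unrounded, unclamped Gaussian draws.
#' @return Integer outcomes in `[outcome_min, outcome_max]` (or numeric
#'   draws when `raw = TRUE`).
#' @export
#' @examples
#' cfg <- task_config(trials_per_session = 10)
#' set.seed(1)
#' sample_outcome(5, cfg, n = 5)
sample_outcome <- function(mean, config, n = 1L, raw = FALSE) {
  stopifnot(inherits(config, "task_config"))
  if (mean < config$mean_low || mean > config$mean_high) {
    stopf("`mean` (%s) outside the configured mean range [%s, %s]",
          mean, config$mean_low, config$mean_high)
  }
  x <- stats::rnorm(n, mean, config$outcome_sd)
  if (raw) return(x)
  as.integer(pmin(pmax(floor(x + 0.5), config$outcome_min), config$outcome_max))
}

#' Generate the trial structure of one horizon-task session
#'
#' Produces trials with alternating horizon blocks of exactly
#' `block_length` trials, per-trial true means drawn independently and
#' uniformly in the configured range (redrawn until distinct after rounding
#' to `mean_step`), and an observation phase in which exactly half of the
#' trials carry an equal information split (e.g. 2/2 of 4 samples) and the
#' other half an unequal split (3/1), with the information-rich side
#' randomised. No choices are made; see [simulate_agent()].
#'
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give byte-identical sessions.
#' @param session_id,animal_id Identifiers carried into downstream tables.
#' @return An object of class `horizon_session`: a list with `trials` (one
#'   row per trial, observation values as list columns) and an empty
#'   `choices` table.
#' @export
#' @examples
#' s <- generate_session(task_config(trials_per_session = 20), seed = 1)
#' table(rle(s$trials$horizon)$lengths)
generate_session <- function(config, seed, session_id = "s01", animal_id = "m1") {
  stopifnot(inherits(config, "task_config"))
  n <- config$trials_per_session
  with_seed(seed, {
    # Alternating horizon blocks; the starting horizon is randomised.
    n_blocks <- n %/% config$block_length
    start_short <- stats::runif(1) < 0.5
    horizons <- rep(
      rep(c(config$horizon_short, config$horizon_long),
          length.out = n_blocks),
      each = config$block_length
    )
    if (!start_short) horizons <- rev(horizons)

    # Exactly half the trials get the equal split, shuffled across the session.
    equal_split <- sample(rep(c(TRUE, FALSE), each = n %/% 2L))

    trials <- data.frame(
      trial_id = seq_len(n),
      horizon = horizons,
      block = rep(seq_len(n_blocks), each = config$block_length),
      equal_split = equal_split,
      true_mean_left = NA_real_,
      true_mean_right = NA_real_
    )
    obs_left <- vector("list", n)
    obs_right <- vector("list", n)

    half <- config$n_observations %/% 2L
    for (i in seq_len(n)) {
      repeat {
        mu <- stats::runif(2, config$mean_low, config$mean_high)
        if (round(mu[1] / config$mean_step) != round(mu[2] / config$mean_step)) break
      }
      trials$true_mean_left[i] <- mu[1]
      trials$true_mean_right[i] <- mu[2]
      if (equal_split[i]) {
        n_left <- half
      } else {
        # Unequal split: one side gets all but one sample; side randomised.
        n_left <- if (stats::runif(1) < 0.5) config$n_observations - 1L else 1L
      }
      n_right <- config$n_observations - n_left
      obs_left[[i]] <- sample_outcome(mu[1], config, n = n_left)
      obs_right[[i]] <- sample_outcome(mu[2], config, n = n_right)
    }
    trials$obs_left <- I(obs_left)
    trials$obs_right <- I(obs_right)

    structure(
      list(session_id = session_id,
           animal_id = animal_id,
           feedback = config$feedback,
           config = config,
           seed = seed,
           trials = trials,
           choices = empty_choices()),
      class = "horizon_session"
    )
  })
}

empty_choices <- function() {
  data.frame(trial_id = integer(), choice_index = integer(),
             side = character(), chosen_outcome = integer(),
             unchosen_outcome = integer())
}

#' @export
print.horizon_session <- function(x, ...) {
  cat(sprintf("Horizon-task session %s (animal %s, %s feedback)\n",
              x$session_id, x$animal_id, x$feedback))
  cat(sprintf("  %d trials (%d short, %d long horizon), %d choices recorded\n",
              nrow(x$trials),
              sum(x$trials$horizon == x$config$horizon_short),
              sum(x$trials$horizon == x$config$horizon_long),
              nrow(x$choices)))
  invisible(x)
}

#' Simulate a choice-making agent on a generated session
#'
#' At every choice point the agent evaluates the current beliefs of the
#' ideal Bayesian observer, forms the linear predictor of the first-choice
#' model (choice 1 of every trial) or the subsequent-choice model (choices
#' 2+ of long-horizon trials) with the coefficients in `params`, passes it
#' through the logistic function mixed with `lapse_rate` uniform choice,
#' samples a side, then samples outcomes for both sides and updates beliefs
#' before the next choice. The unchosen outcome is recorded only under
#' complete feedback; under partial feedback it is drawn but discarded, so
#' it can never inform later choices.
#'
#' @param session A `horizon_session` from [generate_session()].
#' @param params An [agent_params()].
#' @param observer An [observer_config()] used to compute decision
#'   variables online.
#' @param seed Integer seed for the agent's choice and outcome randomness.
#' @return The session with its `choices` table filled.
#' @export
simulate_agent <- function(session, params, observer, seed) {
  stopifnot(inherits(session, "horizon_session"),
            inherits(params, "agent_params"),
            inherits(observer, "observer_config"))
  cfg <- session$config
  complete <- identical(session$feedback, "complete")
  with_seed(seed, {
    rows <- vector("list", sum(session$trials$horizon))
    r <- 0L
    prev_last_side <- NA_character_
    for (i in seq_len(nrow(session$trials))) {
      tr <- session$trials[i, ]
      obs_l <- tr$obs_left[[1]]
      obs_r <- tr$obs_right[[1]]
      base_l <- belief_state(obs_l, observer)
      base_r <- belief_state(obs_r, observer)
      # Feedback streams: chosen-only (b) and full incl. counterfactual (c).
      b_l <- obs_l; b_r <- obs_r
      c_l <- obs_l; c_r <- obs_r
      n_right_chosen <- 0L
      n_left_chosen <- 0L
      last_side <- NA_character_
      for (k in seq_len(tr$horizon)) {
        if (k == 1L) {
          rb <- rb_code(prev_last_side)
          hz <- if (tr$horizon == cfg$horizon_short) 1 else -1
          reg <- first_choice_row(base_l, base_r, length(obs_l), length(obs_r),
                                  hz, rb, params$variant)
          eta <- sum(params$first * reg)
        } else {
          sb_l <- belief_state(b_l, observer)
          sb_r <- belief_state(b_r, observer)
          sc_l <- if (complete) belief_state(c_l, observer) else sb_l
          sc_r <- if (complete) belief_state(c_r, observer) else sb_r
          reg <- subsequent_choice_row(
            base_l, base_r, sb_l, sb_r, sc_l, sc_r,
            dchosen = n_right_chosen - n_left_chosen,
            rb = rb_code(last_side)
          )
          eta <- sum(params$subsequent * reg)
        }
        p_right <- (1 - params$lapse_rate) * stats::plogis(eta) +
          params$lapse_rate * 0.5
        side <- if (stats::runif(1) < p_right) "right" else "left"
        out_l <- sample_outcome(tr$true_mean_left, cfg)
        out_r <- sample_outcome(tr$true_mean_right, cfg)
        chosen <- if (side == "right") out_r else out_l
        unchosen <- if (side == "right") out_l else out_r
        r <- r + 1L
        rows[[r]] <- data.frame(
          trial_id = tr$trial_id, choice_index = k, side = side,
          chosen_outcome = chosen,
          unchosen_outcome = if (complete) unchosen else NA_integer_
        )
        if (side == "right") {
          b_r <- c(b_r, out_r); c_r <- c(c_r, out_r)
          if (complete) c_l <- c(c_l, out_l)
          n_right_chosen <- n_right_chosen + 1L
        } else {
          b_l <- c(b_l, out_l); c_l <- c(c_l, out_l)
          if (complete) c_r <- c(c_r, out_r)
          n_left_chosen <- n_left_chosen + 1L
        }
        last_side <- side
      }
      prev_last_side <- last_side
    }
    session$choices <- do.call(rbind, rows[seq_len(r)])
    session
  })
}

rb_code <- function(side) {
  if (is.na(side)) 0 else if (side == "right") 1 else -1
}

#' Simulate a multi-animal, multi-session horizon-task experiment
#'
#' Generates and simulates sessions for each animal under the requested
#' feedback conditions, mirroring the study's scale of three animals and
#' roughly 13 sessions per condition.
#'
#' @param params An [agent_params()], or a function
#'   `function(animal_id, feedback)` returning one, so that coefficients
#'   can differ by animal and condition.
#' @param config A [task_config()]; its `feedback` field is overridden per
#'   condition.
#' @param observer An [observer_config()].
#' @param animals Character vector of animal identifiers.
#' @param sessions_per_condition Sessions per animal and feedback condition.
#' @param feedback Conditions to simulate.
#' @param seed Integer master seed; per-session seeds are derived from it.
#' @return A list of `horizon_session` objects.
#' @export
simulate_experiment <- function(params,
                                config = task_config(),
                                observer = observer_config(sigma = config$outcome_sd),
                                animals = paste0("m", 1:3),
                                sessions_per_condition = 13L,
                                feedback = c("partial", "complete"),
                                seed = 1L) {
  feedback <- match.arg(feedback, several.ok = TRUE)
  param_fun <- if (is.function(params)) {
    params
  } else {
    stopifnot(inherits(params, "agent_params"))
    function(animal_id, fb) params
  }
  n_total <- length(animals) * length(feedback) * sessions_per_condition
  seeds <- derive_seeds(seed, 2L * n_total)
  sessions <- vector("list", n_total)
  i <- 0L
  for (fb in feedback) {
    cfg <- config
    cfg$feedback <- fb
    for (an in animals) {
      pa <- param_fun(an, fb)
      stopifnot(inherits(pa, "agent_params"))
      for (s in seq_len(sessions_per_condition)) {
        i <- i + 1L
        sid <- sprintf("%s_%s_s%02d", an, fb, s)
        ses <- generate_session(cfg, seed = seeds[2L * i - 1L],
                                session_id = sid, animal_id = an)
        sessions[[i]] <- simulate_agent(ses, pa, observer, seed = seeds[2L * i])
      }
    }
  }
  sessions
}
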