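#' Task configuration for the horizon task generator
#'
#' Bundles the generative constants of the sequential two-option choice task:
#' per-option reward means drawn uniformly in `[mean_low, mean_high]` drops,
#' integer outcomes in `[outcome_min, outcome_max]` obtained by rounding a
#' Gaussian draw with SD `outcome_sd`, an observation phase of
#' `n_observations` informative samples (at least one per side), and horizon
#' blocks of `block_length` consecutive trials alternating between
#' `horizon_short` and `horizon_long` choices per trial. Feedback after an
#' active choice is either `"partial"` (chosen outcome only) or `"complete"`
#' (both outcomes; the unchosen one is counterfactual), fixed per session.
#'
#' @param outcome_sd Gaussian SD of outcome draws, in drops (default 1.5).
#' @param mean_low,mean_high Range of the per-option true means, in drops.
#' @param outcome_min,outcome_max Integer outcome support bounds, in drops.
#' @param n_observations Number of informative observation-phase samples per
#'   trial (must be even so that an exactly equal split exists).
#' @param block_length Number of consecutive equal-horizon trials per block.
#' @param horizon_short,horizon_long Number of choices in short / long
#'   horizon trials.
#' @param feedback `"partial"` or `"complete"`; fixed for the whole session.
#' @param trials_per_session Trials per session; must be a multiple of
#'   `2 * block_length` so horizons and information splits balance exactly.
#' @param mean_step Grid step used to decide that two true means are
#'   distinct (means are redrawn until they differ after rounding to this
#'   step).
#' @return An object of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config(trials_per_session = 20, feedback = "partial")
#' cfg$outcome_sd
task_config <- function(outcome_sd = 1.5,
                        mean_low = 3,
                        mean_high = 7,
                        outcome_min = 0L,
                        outcome_max = 10L,
                        n_observations = 4L,
                        block_length = 5L,
                        horizon_short = 1L,
                        horizon_long = 4L,
                        feedback = c("partial", "complete"),
                        trials_per_session = 100L,
                        mean_step = 0.05) {
  feedback <- match.arg(feedback)
  if (!is.numeric(outcome_sd) || outcome_sd < 0) {
    stopf("`outcome_sd` must be a non-negative number")
  }
  if (outcome_min >= outcome_max) stopf("`outcome_min` must be < `outcome_max`")
  if (mean_low < outcome_min || mean_high > outcome_max) {
    stopf("mean range [%s, %s] must lie within the outcome support [%s, %s]",
          mean_low, mean_high, outcome_min, outcome_max)
  }
  if (!is_count(n_observations) || n_observations < 2) {
    stopf("`n_observations` must be an integer >= 2 (each option needs >= 1 sample)")
  }
  if (n_observations %% 2 != 0) {
    stopf("`n_observations` must be even so that an equal information split exists")
  }
  if (!is_count(block_length)) stopf("`block_length` must be a positive integer")
  if (!is_count(horizon_short) || !is_count(horizon_long) ||
      horizon_short >= horizon_long) {
    stopf("`horizon_short` must be a positive integer < `horizon_long`")
  }
  if (!is_count(trials_per_session)) {
    stopf("`trials_per_session` must be a positive integer")
  }
  if (trials_per_session %% (2L * block_length) != 0) {
    stopf(paste("`trials_per_session` (%d) must be a multiple of 2 x block_length (%d)",
                "so that horizons and information splits can be balanced exactly"),
          trials_per_session, 2L * block_length)
  }
  structure(
    list(outcome_sd = outcome_sd,
         mean_low = mean_low, mean_high = mean_high,
         outcome_min = as.integer(outcome_min),
         outcome_max = as.integer(outcome_max),
         n_observations = as.integer(n_observations),
         block_length = as.integer(block_length),
         horizon_short = as.integer(horizon_short),
         horizon_long = as.integer(horizon_long),
         feedback = feedback,
         trials_per_session = as.integer(trials_per_session),
         mean_step = mean_step),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Horizon task configuration\n")
  cat(sprintf("  outcomes: integers in [%d, %d] drops, Gaussian SD %.2f\n",
              x$outcome_min, x$outcome_max, x$outcome_sd))
  cat(sprintf("  true means: uniform in [%.1f, %.1f] drops\n", x$mean_low, x$mean_high))
  cat(sprintf("  observation phase: %d informative samples (>= 1 per side)\n",
              x$n_observations))
  cat(sprintf("  horizons: short = %d, long = %d choices; blocks of %d trials\n",
              x$horizon_short, x$horizon_long, x$block_length))
  cat(sprintf("  feedback: %s; trials per session: %d\n",
              x$feedback, x$trials_per_session))
  invisible(x)
}

# Coefficient names of the two choice models. "U" holds the uncertainty
# difference or, under the information-count variant, the difference in the
# number of informative observations.
first_choice_coefs <- function() {
  c("SB", "RB", "horizon", "EV", "U", "EVxhorizon", "Uxhorizon")
}

subsequent_choice_coefs <- function() {
  c("SB", "RB", "dChosen", "baselineEV", "dEVchosen", "baselineU",
    "dUchosen", "dEVunchosen", "dUunchosen")
}

#' Ground-truth coefficients for a simulated choice-making agent
#'
#' Holds one coefficient per regressor of the first-choice model
#' (side bias `SB`, repetition bias `RB`, `horizon`, expected-value
#' difference `EV`, uncertainty (or information-count) difference `U`, and
#' the two horizon interactions) and of the subsequent-choice model
#' (`SB`, `RB`, signed choice count `dChosen`, observation-phase baselines
#' `baselineEV`/`baselineU`, chosen-feedback updates `dEVchosen`/`dUchosen`,
#' and counterfactual updates `dEVunchosen`/`dUunchosen`). The agent passes
#' the linear predictor through a logistic function mixed with a
#' `lapse_rate` of uniform random choice.
#'
#' @param first Named numeric vector of first-choice coefficients; missing
#'   names default to 0.
#' @param subsequent Named numeric vector of subsequent-choice coefficients;
#'   missing names default to 0.
#' @param lapse_rate Probability in `[0, 0.5)` of a uniform random choice.
#' @param variant `"uncertainty"` (the `U` regressor is the predictive
#'   variance difference) or `"info_count"` (the difference in the number of
#'   informative observations).
#' @return An object of class `agent_params`.
#' @export
#' @examples
#' agent_params(first = c(EV = 1.5), lapse_rate = 0)
agent_params <- function(first = NULL, subsequent = NULL, lapse_rate = 0,
                         variant = c("uncertainty", "info_count")) {
  variant <- match.arg(variant)
  fill <- function(x, nm, what) {
    out <- stats::setNames(numeric(length(nm)), nm)
    if (is.null(x)) return(out)
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stopf("`%s` coefficients must be named", what)
    }
    bad <- setdiff(names(x), nm)
    if (length(bad)) {
      stopf("unknown %s coefficient(s): %s (expected among %s)",
            what, paste(bad, collapse = ", "), paste(nm, collapse = ", "))
    }
    if (any(!is.finite(x))) stopf("`%s` coefficients must be finite", what)
    out[names(x)] <- x
    out
  }
  if (!is.numeric(lapse_rate) || length(lapse_rate) != 1L ||
      lapse_rate < 0 || lapse_rate >= 0.5) {
    stopf("`lapse_rate` must be a single probability in [0, 0.5)")
  }
  structure(
    list(first = fill(first, first_choice_coefs(), "first"),
         subsequent = fill(subsequent, subsequent_choice_coefs(), "subsequent"),
         lapse_rate = lapse_rate,
         variant = variant),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Agent parameters (", x$variant, " variant, lapse ", x$lapse_rate, ")\n", sep = "")
  cat("  first-choice:\n")
  print(round(x$first, 3))
  cat("  subsequent-choice:\n")
  print(round(x$subsequent, 3))
  invisible(x)
}
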