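#' Configuration of the ideal Bayesian observer
#'
#' The observer assumes each option's outcomes are i.i.d. draws from a
#' discretised Gaussian of unknown mean and known SD `sigma`. Candidate
#' means live on `mean_grid`; outcomes live on the integer support
#' `outcome_support`. For each candidate mean the likelihood is the
#' Gaussian kernel evaluated at the support values and normalised over the
#' support, so each likelihood column sums to one exactly. The prior over
#' candidate means defaults to uniform. The grid deliberately spans the
#' whole outcome range rather than the generative mean range: the observer
#' only sees what is on the screen and is not told where true means can
#' fall.
#'
#' @param mean_grid Strictly increasing candidate means, in drops.
#' @param sigma Likelihood SD, in drops (default 1.5).
#' @param outcome_support Ordered integer outcome values, in drops.
#' @param prior Probability vector over `mean_grid`; default uniform. Must
#'   sum to 1 within 1e-12.
#' @return An object of class `observer_config` with precomputed
#'   log-likelihood and likelihood matrices (`support x grid`).
#' @export
#' @examples
#' oc <- observer_config()
#' colSums(oc$lik)[1:3]  # each candidate mean's likelihood sums to 1
observer_config <- function(mean_grid = seq(0, 10, by = 0.05),
                            sigma = 1.5,
                            outcome_support = 0:10,
                            prior = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stopf("`sigma` must be a single positive number")
  }
  if (any(diff(mean_grid) <= 0)) stopf("`mean_grid` must be strictly increasing")
  if (any(diff(outcome_support) <= 0)) {
    stopf("`outcome_support` must be strictly increasing")
  }
  if (is.null(prior)) {
    prior <- rep(1 / length(mean_grid), length(mean_grid))
  }
  if (length(prior) != length(mean_grid)) {
    stopf("`prior` must have one entry per grid point")
  }
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-12) {
    stopf("`prior` must be non-negative and sum to 1 within 1e-12")
  }
  # log-likelihood matrix: rows = outcome support, cols = candidate means,
  # each column normalised over the support.
  ll <- outer(outcome_support, mean_grid,
              function(x, mu) -(x - mu)^2 / (2 * sigma^2))
  ll <- sweep(ll, 2L, apply(ll, 2L, logsumexp))
  structure(
    list(mean_grid = mean_grid, sigma = sigma,
         outcome_support = as.integer(outcome_support),
         prior = prior, log_prior = log(prior),
         log_lik = ll, lik = exp(ll)),
    class = "observer_config"
  )
}

#' @export
print.observer_config <- function(x, ...) {
  cat(sprintf(paste0("Ideal Bayesian observer: %d candidate means in [%g, %g], ",
                     "sigma = %g, outcomes %d..%d\n"),
              length(x$mean_grid), min(x$mean_grid), max(x$mean_grid),
              x$sigma, min(x$outcome_support), max(x$outcome_support)))
  invisible(x)
}

match_support <- function(x, config, what = "observation") {
  idx <- match(x, config$outcome_support)
  if (anyNA(idx)) {
    stopf("%s value(s) outside the outcome support: %s",
          what, paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Likelihood of a single outcome under a candidate mean
#'
#' Returns the normalised discretised-Gaussian likelihood
#' `P(x | mu)` from the observer's precomputed table.
#'
#' @param x An outcome value in the support.
#' @param mu A candidate mean on the grid.
#' @param config An [observer_config()].
#' @return A probability.
#' @export
outcome_likelihood <- function(x, mu, config) {
  stopifnot(inherits(config, "observer_config"))
  ix <- match_support(x, config, "outcome")
  im <- which(abs(config$mean_grid - mu) < 1e-9)
  if (length(im) != 1L) stopf("`mu` (%s) is not on the mean grid", mu)
  config$lik[ix, im]
}

#' Posterior over candidate means given a set of observations
#'
#' Computes `P(mu | x_1..x_n)` proportional to the prior times the product
#' of per-observation likelihoods, in log space with max-subtraction
#' renormalisation. An empty observation set returns the prior.
#'
#' @param observations Integer outcomes in the support (possibly empty).
#' @param config An [observer_config()].
#' @return A probability vector over `config$mean_grid`.
#' @export
#' @examples
#' oc <- observer_config()
#' p <- posterior_over_means(c(4, 6), oc)
#' sum(p * oc$mean_grid)  # posterior mean, 5 by symmetry
posterior_over_means <- function(observations, config) {
  stopifnot(inherits(config, "observer_config"))
  if (length(observations) == 0L) return(config$prior)
  idx <- match_support(observations, config)
  lp <- config$log_prior + colSums(config$log_lik[idx, , drop = FALSE])
  lp <- lp - max(lp)
  p <- exp(lp)
  z <- sum(p)
  if (!is.finite(z) || z <= 0) {
    stopf("posterior has no mass; observations: %s",
          paste(observations, collapse = ", "))
  }
  p / z
}

#' Posterior predictive distribution of the next outcome
#'
#' Mixes the per-mean outcome likelihoods by the posterior:
#' `P(x_next) = sum_j P(x_next | mu_j) P(mu_j | data)`.
#'
#' @param posterior Probability vector over the mean grid.
#' @param config An [observer_config()].
#' @return A probability vector over `config$outcome_support`.
#' @export
predictive_next_outcome <- function(posterior, config) {
  stopifnot(inherits(config, "observer_config"))
  if (length(posterior) != length(config$mean_grid)) {
    stopf("`posterior` must have one entry per grid point")
  }
  if (any(posterior < 0) || abs(sum(posterior) - 1) > 1e-8) {
    stopf("`posterior` must be a normalised probability vector")
  }
  pred <- as.vector(config$lik %*% posterior)
  pred / sum(pred)
}

#' Expected value and uncertainty of a predictive distribution
#'
#' The expected value (EV) is the mean of the posterior predictive over the
#' next outcome; the uncertainty (U) is its variance, in drops squared.
#'
#' @param predictive Probability vector over the outcome support.
#' @param config An [observer_config()].
#' @return A named list with `expected_value` and `uncertainty`.
#' @export
belief_summary <- function(predictive, config) {
  stopifnot(inherits(config, "observer_config"))
  if (length(predictive) != length(config$outcome_support)) {
    stopf("`predictive` must have one entry per outcome support value")
  }
  if (any(predictive < 0) || abs(sum(predictive) - 1) > 1e-8) {
    stopf("`predictive` must be a normalised probability vector")
  }
  x <- config$outcome_support
  ev <- sum(x * predictive)
  list(expected_value = ev, uncertainty = sum((x - ev)^2 * predictive))
}

#' Full belief state of one option after a set of observations
#'
#' @param observations Integer outcomes in the support (possibly empty).
#' @param config An [observer_config()].
#' @return An object of class `belief_state` with the posterior over means,
#'   the predictive over the next outcome, its expected value and
#'   uncertainty, and the observation count.
#' @export
belief_state <- function(observations, config) {
  post <- posterior_over_means(observations, config)
  pred <- predictive_next_outcome(post, config)
  s <- belief_summary(pred, config)
  structure(
    list(posterior = post, predictive = pred,
         expected_value = s$expected_value, uncertainty = s$uncertainty,
         n_observations = length(observations)),
    class = "belief_state"
  )
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Belief state after %d observation(s): EV = %.3f drops, U = %.3f drops^2\n",
              x$n_observations, x$expected_value, x$uncertainty))
  invisible(x)
}

#' Per-choice belief trajectories for one trial
#'
#' For each choice point of a trial with recorded choices, computes the
#' left and right option beliefs under three information streams:
#' `"baseline"` uses the observation phase only; `"chosen"` adds the
#' outcomes of the options the agent chose before the current choice;
#' `"full"` additionally adds the counterfactual (unchosen) outcomes, and
#' differs from `"chosen"` only under complete feedback. Beliefs at choice
#' `k` use only feedback revealed strictly before choice `k`.
#'
#' @param trial A list with integer vectors `obs_left` and `obs_right` and
#'   a `choices` data frame (`choice_index`, `side`, `chosen_outcome`,
#'   `unchosen_outcome`).
#' @param feedback `"partial"` or `"complete"`.
#' @param config An [observer_config()].
#' @return A data frame with one row per (choice, side, stream):
#'   `choice_index`, `side`, `stream`, `EV`, `U`, `n_obs`.
#' @export
belief_trajectory <- function(trial, feedback = c("partial", "complete"), config) {
  feedback <- match.arg(feedback)
  stopifnot(inherits(config, "observer_config"))
  ch <- trial$choices
  ch <- ch[order(ch$choice_index), , drop = FALSE]
  match_support(c(trial$obs_left, trial$obs_right), config)
  complete <- identical(feedback, "complete")
  if (complete && nrow(ch) > 0 && anyNA(ch$unchosen_outcome)) {
    stopf("complete-feedback trial with missing unchosen outcomes")
  }

  streams <- function(k) {
    b_l <- trial$obs_left; b_r <- trial$obs_right
    c_l <- trial$obs_left; c_r <- trial$obs_right
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        if (ch$side[j] == "right") {
          b_r <- c(b_r, ch$chosen_outcome[j]); c_r <- c(c_r, ch$chosen_outcome[j])
          if (complete) c_l <- c(c_l, ch$unchosen_outcome[j])
        } else {
          b_l <- c(b_l, ch$chosen_outcome[j]); c_l <- c(c_l, ch$chosen_outcome[j])
          if (complete) c_r <- c(c_r, ch$unchosen_outcome[j])
        }
      }
    }
    list(b_l = b_l, b_r = b_r, c_l = c_l, c_r = c_r)
  }

  rows <- list()
  for (k in seq_len(nrow(ch))) {
    st <- streams(k)
    sets <- list(
      baseline_left = trial$obs_left, baseline_right = trial$obs_right,
      chosen_left = st$b_l, chosen_right = st$b_r,
      full_left = st$c_l, full_right = st$c_r
    )
    for (nm in names(sets)) {
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      bs <- belief_state(sets[[nm]], config)
      rows[[length(rows) + 1L]] <- data.frame(
        choice_index = ch$choice_index[k], side = parts[2], stream = parts[1],
        EV = bs$expected_value, U = bs$uncertainty, n_obs = bs$n_observations
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(choice_index = integer(), side = character(),
                      stream = character(), EV = numeric(), U = numeric(),
                      n_obs = integer()))
  }
  do.call(rbind, rows)
}

#' Belief trajectories for every trial of a session
#'
#' @param session A `horizon_session` with choices filled.
#' @param config An [observer_config()].
#' @return A tidy data frame: `session_id`, `trial_id`, `choice_index`,
#'   `side`, `stream`, `EV`, `U`, `n_obs`.
#' @export
session_beliefs <- function(session, config) {
  stopifnot(inherits(session, "horizon_session"))
  out <- lapply(seq_len(nrow(session$trials)), function(i) {
    tr <- trial_record(session, i)
    bt <- belief_trajectory(tr, session$feedback, config)
    if (nrow(bt) == 0L) return(NULL)
    cbind(session_id = session$session_id,
          trial_id = session$trials$trial_id[i], bt)
  })
  do.call(rbind, out)
}

# Extract one trial (structure + its choices) from a session.
trial_record <- function(session, i) {
  tr <- session$trials[i, ]
  list(trial_id = tr$trial_id,
       horizon = tr$horizon,
       obs_left = tr$obs_left[[1]],
       obs_right = tr$obs_right[[1]],
       true_mean_left = tr$true_mean_left,
       true_mean_right = tr$true_mean_right,
       choices = session$choices[session$choices$trial_id == tr$trial_id, ,
                                 drop = FALSE])
}
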