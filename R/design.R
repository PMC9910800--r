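# Regressor construction for the two logistic choice models. The same row
# helpers are used by the simulator's generative agent and by the design
# builders, so the fitted design is the exact inverse of the generative
# linear predictor.

# One first-choice regressor row. All difference regressors are
# right-minus-left. `horizon` is coded +1 short / -1 long; `rb` is +1 if
# the previous completed trial ended with a right choice, -1 left, 0 none.
first_choice_row <- function(bs_left, bs_right, n_left, n_right,
                             horizon, rb, variant) {
  ev <- bs_right$expected_value - bs_left$expected_value
  u <- if (identical(variant, "info_count")) {
    n_right - n_left
  } else {
    bs_right$uncertainty - bs_left$uncertainty
  }
  c(SB = 1, RB = rb, horizon = horizon, EV = ev, U = u,
    EVxhorizon = ev * horizon, Uxhorizon = u * horizon)
}

# One subsequent-choice regressor row. Baselines come from the
# observation-phase stream; the chosen-update terms are the chosen-only
# stream minus baseline; the counterfactual terms are full stream minus
# chosen-only stream (zero under partial feedback). `dchosen` is the signed
# right-minus-left choice count so far within the trial; `rb` codes the
# previous choice's side.
subsequent_choice_row <- function(base_left, base_right,
                                  chosen_left, chosen_right,
                                  full_left, full_right,
                                  dchosen, rb) {
  base_ev <- base_right$expected_value - base_left$expected_value
  base_u <- base_right$uncertainty - base_left$uncertainty
  b_ev <- chosen_right$expected_value - chosen_left$expected_value
  b_u <- chosen_right$uncertainty - chosen_left$uncertainty
  c_ev <- full_right$expected_value - full_left$expected_value
  c_u <- full_right$uncertainty - full_left$uncertainty
  c(SB = 1, RB = rb, dChosen = dchosen,
    baselineEV = base_ev, dEVchosen = b_ev - base_ev,
    baselineU = base_u, dUchosen = b_u - base_u,
    dEVunchosen = c_ev - b_ev, dUunchosen = c_u - b_u)
}

check_sessions <- function(sessions) {
  if (inherits(sessions, "horizon_session")) sessions <- list(sessions)
  for (s in sessions) {
    stopifnot(inherits(s, "horizon_session"))
    if (nrow(s$choices) == 0L) {
      stopf("session %s has no recorded choices; run simulate_agent() first",
            s$session_id)
    }
    partial_na <- is.na(s$choices$unchosen_outcome)
    if (identical(s$feedback, "partial") && !all(partial_na)) {
      stopf("partial-feedback session %s contains unchosen outcomes", s$session_id)
    }
    if (identical(s$feedback, "complete") && any(partial_na)) {
      stopf("complete-feedback session %s is missing unchosen outcomes",
            s$session_id)
    }
  }
  sessions
}

#' Build the first-choice design matrix
#'
#' One row per first choice of every trial (both horizons, both feedback
#' conditions). The regressors are the side-bias intercept `SB`, the
#' repetition bias `RB` (side of the previous completed trial's last
#' choice, 0 for the first trial of a session), the horizon code (+1 short,
#' -1 long), the right-minus-left expected-value difference `EV`, the
#' right-minus-left uncertainty difference `U` (or, under the
#' `info_count` variant, the difference in the number of informative
#' observations), and the products of the horizon code with `EV` and `U`.
#' The response is 1 when the right option was chosen.
#'
#' @param sessions A `horizon_session` or list of them, with choices filled.
#' @param observer An [observer_config()]; beliefs are computed from the
#'   observation phase only.
#' @param variant `"uncertainty"` or `"info_count"`.
#' @return A data frame with grouping columns (`animal_id`, `session_id`,
#'   `feedback`, `choice_kind`, `trial_id`), the regressor columns and the
#'   binary `response`. The regressor schema is attached as
#'   `attr(, "regressors")` and the variant as `attr(, "variant")`.
#' @export
build_first_choice_design <- function(sessions, observer,
                                      variant = c("uncertainty", "info_count")) {
  variant <- match.arg(variant)
  stopifnot(inherits(observer, "observer_config"))
  sessions <- check_sessions(sessions)
  out <- lapply(sessions, function(s) {
    cfg <- s$config
    n_tr <- nrow(s$trials)
    rows <- vector("list", n_tr)
    prev_last_side <- NA_character_
    for (i in seq_len(n_tr)) {
      tr <- trial_record(s, i)
      if (nrow(tr$choices) == 0L) next
      first <- tr$choices[tr$choices$choice_index == 1L, ]
      bs_l <- belief_state(tr$obs_left, observer)
      bs_r <- belief_state(tr$obs_right, observer)
      hz <- if (tr$horizon == cfg$horizon_short) 1 else -1
      reg <- first_choice_row(bs_l, bs_r, length(tr$obs_left),
                              length(tr$obs_right), hz,
                              rb_code(prev_last_side), variant)
      rows[[i]] <- data.frame(
        animal_id = s$animal_id, session_id = s$session_id,
        feedback = s$feedback, choice_kind = "first",
        trial_id = tr$trial_id, t(reg),
        response = as.integer(first$side == "right")
      )
      prev_last_side <- tr$choices$side[nrow(tr$choices)]
    }
    do.call(rbind, rows)
  })
  design <- do.call(rbind, out)
  if (any(!is.finite(as.matrix(design[, first_choice_coefs()])))) {
    stopf("non-finite regressor values in the first-choice design")
  }
  attr(design, "regressors") <- first_choice_coefs()
  attr(design, "variant") <- variant
  design
}

#' Build the subsequent-choice design matrix
#'
#' One row per second, third and fourth choice of every long-horizon trial.
#' Regressors: `SB` (intercept), `RB` (side of the previous choice within
#' the trial), `dChosen` (signed right-minus-left choice count so far in
#' the trial), `baselineEV`/`baselineU` (right-minus-left expected value /
#' uncertainty from the observation phase), `dEVchosen`/`dUchosen` (current
#' chosen-feedback beliefs minus baseline) and `dEVunchosen`/`dUunchosen`
#' (full-information beliefs minus chosen-only beliefs; identically zero
#' under partial feedback). Beliefs at choice k use only feedback revealed
#' strictly before choice k.
#'
#' When every session is partial-feedback, the counterfactual columns are
#' dropped from the fitted schema (they are identically zero) but kept in
#' the data frame.
#'
#' @inheritParams build_first_choice_design
#' @return A data frame as in [build_first_choice_design()] with
#'   `choice_kind = "subsequent"`.
#' @export
build_subsequent_choice_design <- function(sessions, observer) {
  stopifnot(inherits(observer, "observer_config"))
  sessions <- check_sessions(sessions)
  out <- lapply(sessions, function(s) {
    cfg <- s$config
    complete <- identical(s$feedback, "complete")
    rows <- list()
    for (i in seq_len(nrow(s$trials))) {
      tr <- trial_record(s, i)
      if (tr$horizon != cfg$horizon_long || nrow(tr$choices) < 2L) next
      ch <- tr$choices[order(tr$choices$choice_index), ]
      base_l <- belief_state(tr$obs_left, observer)
      base_r <- belief_state(tr$obs_right, observer)
      b_l <- tr$obs_left; b_r <- tr$obs_right
      c_l <- tr$obs_left; c_r <- tr$obs_right
      n_right <- 0L; n_left <- 0L
      for (k in seq_len(nrow(ch))) {
        if (k > 1L) {
          sb_l <- belief_state(b_l, observer)
          sb_r <- belief_state(b_r, observer)
          sc_l <- if (complete) belief_state(c_l, observer) else sb_l
          sc_r <- if (complete) belief_state(c_r, observer) else sb_r
          reg <- subsequent_choice_row(base_l, base_r, sb_l, sb_r, sc_l, sc_r,
                                       dchosen = n_right - n_left,
                                       rb = rb_code(ch$side[k - 1L]))
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = s$animal_id, session_id = s$session_id,
            feedback = s$feedback, choice_kind = "subsequent",
            trial_id = tr$trial_id, choice_index = ch$choice_index[k], t(reg),
            response = as.integer(ch$side[k] == "right")
          )
        }
        if (ch$side[k] == "right") {
          b_r <- c(b_r, ch$chosen_outcome[k]); c_r <- c(c_r, ch$chosen_outcome[k])
          if (complete) c_l <- c(c_l, ch$unchosen_outcome[k])
          n_right <- n_right + 1L
        } else {
          b_l <- c(b_l, ch$chosen_outcome[k]); c_l <- c(c_l, ch$chosen_outcome[k])
          if (complete) c_r <- c(c_r, ch$unchosen_outcome[k])
          n_left <- n_left + 1L
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  design <- do.call(rbind, out)
  if (is.null(design) || nrow(design) == 0L) {
    stopf(paste("no long-horizon trials with >= 2 choices in the input;",
                "the subsequent-choice model applies to long-horizon choices 2+"))
  }
  regs <- subsequent_choice_coefs()
  if (all(design$feedback == "partial")) {
    regs <- setdiff(regs, c("dEVunchosen", "dUunchosen"))
  }
  if (any(!is.finite(as.matrix(design[, subsequent_choice_coefs()])))) {
    stopf("non-finite regressor values in the subsequent-choice design")
  }
  attr(design, "regressors") <- regs
  attr(design, "variant") <- "uncertainty"
  design
}

#' Write a design matrix with its schema sidecar
#'
#' Serialises a design as a tidy CSV plus a JSON sidecar naming the
#' regressor schema, variant and coding conventions.
#'
#' @param design Output of a design builder.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  schema <- list(
    regressors = attr(design, "regressors"),
    variant = attr(design, "variant"),
    coding = list(
      horizon = "+1 short / -1 long",
      RB = "+1 previous choice right / -1 left / 0 none",
      differences = "right minus left",
      response = "1 = right option chosen"
    ),
    columns = names(design)
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a design matrix written by [write_design()]
#'
#' @param path CSV path.
#' @return The design data frame with its schema attributes restored.
#' @export
read_design <- function(path) {
  design <- utils::read.csv(path)
  sidecar <- paste0(path, ".schema.json")
  if (file.exists(sidecar)) {
    schema <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(design, "regressors") <- schema$regressors
    attr(design, "variant") <- schema$variant
  }
  design
}
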