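#' Model-defined choice accuracy
#'
#' A choice is scored correct when the chosen side has the strictly higher
#' expected value under the observer at that moment: the observation-phase
#' beliefs for first choices and the full-information stream (chosen plus
#' any counterfactual feedback revealed so far) for subsequent choices.
#' Exact EV ties are excluded from the denominator (ties are detected up
#' to floating-point resolution, 1e-12 drops). Proportions are computed
#' per session, then averaged across sessions within each (feedback,
#' horizon, choice index) cell.
#'
#' @param sessions A `horizon_session` or list of them, with choices.
#' @param observer An [observer_config()] (the same one used for fitting).
#' @return A list with `per_session` (one row per session x cell) and
#'   `by_cell` (session-averaged accuracy with SEM and session count).
#' @export
accuracy_table <- function(sessions, observer) {
  sc <- score_choices(sessions, observer)
  sc <- sc[!is.na(sc$correct), ]
  aggregate_choice_metric(sc, "correct", "accuracy")
}

# Per-choice accuracy scoring shared with the trend test.
score_choices <- function(sessions, observer) {
  sessions <- check_sessions(sessions)
  out <- lapply(sessions, function(s) {
    cfg <- s$config
    rows <- lapply(seq_len(nrow(s$trials)), function(i) {
      tr <- trial_record(s, i)
      if (nrow(tr$choices) == 0L) return(NULL)
      bt <- belief_trajectory(tr, s$feedback, observer)
      ch <- tr$choices[order(tr$choices$choice_index), ]
      correct <- vapply(seq_len(nrow(ch)), function(k) {
        stream <- if (ch$choice_index[k] == 1L) "baseline" else "full"
        sel <- bt$choice_index == ch$choice_index[k] & bt$stream == stream
        ev_l <- bt$EV[sel & bt$side == "left"]
        ev_r <- bt$EV[sel & bt$side == "right"]
        if (abs(ev_l - ev_r) < 1e-12) return(NA)  # EV tie: excluded
        (ch$side[k] == "right") == (ev_r > ev_l)
      }, logical(1))
      data.frame(session_id = s$session_id, animal_id = s$animal_id,
                 feedback = s$feedback,
                 horizon = if (tr$horizon == cfg$horizon_short) "short" else "long",
                 trial_id = tr$trial_id, choice_index = ch$choice_index,
                 side = ch$side, correct = correct)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

aggregate_choice_metric <- function(df, value_col, out_name) {
  per_session <- stats::aggregate(
    df[[value_col]],
    by = df[c("session_id", "feedback", "horizon", "choice_index")],
    FUN = mean
  )
  names(per_session)[names(per_session) == "x"] <- out_name
  by_cell <- do.call(rbind, lapply(
    split(per_session,
          per_session[c("feedback", "horizon", "choice_index")], drop = TRUE),
    function(g) {
      data.frame(feedback = g$feedback[1], horizon = g$horizon[1],
                 choice_index = g$choice_index[1],
                 n_sessions = nrow(g),
                 value = mean(g[[out_name]]),
                 sem = stats::sd(g[[out_name]]) / sqrt(nrow(g)))
    }
  ))
  names(by_cell)[names(by_cell) == "value"] <- out_name
  rownames(by_cell) <- NULL
  list(per_session = per_session, by_cell = by_cell)
}

#' One-sample t test of per-session values against a null mean
#'
#' Two-sided one-sample t statistic with `n - 1` degrees of freedom, as
#' used to compare session-level accuracy or repetition proportions to
#' chance. Zero-variance inputs are reported as a degenerate case rather
#' than an error: `t = 0, p = 1` when every value equals the null, signed
#' infinite `t` with `p = 0` otherwise.
#'
#' @param values Per-session values (length >= 2).
#' @param null_mean Null hypothesis mean (e.g. 0.5 for chance accuracy).
#' @return A list with `t`, `dof`, `p` and a `degenerate` flag.
#' @export
#' @examples
#' session_ttest(c(0.6, 0.7, 0.8), 0.5)$t  # 2 * sqrt(3)
session_ttest <- function(values, null_mean) {
  if (length(values) < 2L) stopf("need at least 2 sessions for a t test")
  if (stats::sd(values) == 0) {
    if (values[1] == null_mean) {
      return(list(t = 0, dof = length(values) - 1L, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(values[1] - null_mean) * Inf,
                dof = length(values) - 1L, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = null_mean)
  list(t = unname(tt$statistic), dof = as.integer(unname(tt$parameter)),
       p = tt$p.value, degenerate = FALSE)
}

#' Within-horizon trend of accuracy or repetition
#'
#' For each session, regresses the per-choice quantity on the choice index
#' within long-horizon trials (both z-scored; with both variables
#' standardised the OLS slope equals the correlation, so the direction of
#' the regression is immaterial), then t-tests the per-session slopes
#' against zero. Accuracy uses choices 1-4, repetition choices 2-4.
#' Sessions where the quantity or the index is constant have an undefined
#' slope and are dropped, with their ids recorded in `dropped`.
#'
#' @param sessions A `horizon_session` or list of them.
#' @param quantity `"accuracy"` or `"repetition"`.
#' @param observer An [observer_config()]; required for accuracy.
#' @return A list with `slopes` (per-session), `ttest` (group-level
#'   [session_ttest()] against 0, `NULL` if fewer than 2 usable sessions)
#'   and `dropped` (ids of degenerate sessions).
#' @export
within_horizon_trend <- function(sessions, quantity = c("accuracy", "repetition"),
                                 observer = NULL) {
  quantity <- match.arg(quantity)
  sessions <- check_sessions(sessions)
  if (quantity == "accuracy") {
    if (is.null(observer)) stopf("`observer` is required for the accuracy trend")
    df <- score_choices(sessions, observer)
    df <- df[df$horizon == "long" & !is.na(df$correct), ]
    df$value <- as.numeric(df$correct)
  } else {
    df <- repetition_indicators(sessions)
    df$value <- as.numeric(df$repeated)
  }
  slopes <- list()
  dropped <- character()
  for (sid in unique(df$session_id)) {
    g <- df[df$session_id == sid, ]
    if (stats::sd(g$value) == 0 || stats::sd(g$choice_index) == 0) {
      dropped <- c(dropped, sid)
      next
    }
    slopes[[length(slopes) + 1L]] <- data.frame(
      session_id = sid, feedback = g$feedback[1],
      slope = stats::cor(scale(g$value)[, 1], scale(g$choice_index)[, 1])
    )
  }
  slopes <- if (length(slopes)) do.call(rbind, slopes) else
    data.frame(session_id = character(), feedback = character(), slope = numeric())
  tt <- if (nrow(slopes) >= 2L) session_ttest(slopes$slope, 0) else NULL
  list(slopes = slopes, ttest = tt, dropped = dropped)
}

repetition_indicators <- function(sessions) {
  sessions <- check_sessions(sessions)
  out <- lapply(sessions, function(s) {
    cfg <- s$config
    rows <- lapply(seq_len(nrow(s$trials)), function(i) {
      tr <- trial_record(s, i)
      if (tr$horizon != cfg$horizon_long || nrow(tr$choices) < 2L) return(NULL)
      ch <- tr$choices[order(tr$choices$choice_index), ]
      k <- seq.int(2L, nrow(ch))
      data.frame(session_id = s$session_id, feedback = s$feedback,
                 horizon = "long", trial_id = tr$trial_id,
                 choice_index = ch$choice_index[k],
                 repeated = ch$side[k] == ch$side[k - 1L])
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Choice repetition rates across the long horizon
#'
#' The probability that choice k repeats the side of choice k-1 (long
#' horizon, choices 2-4), per session and then averaged across sessions
#' within each (feedback, choice index) cell.
#'
#' @param sessions A `horizon_session` or list of them.
#' @return A list with `per_session` and `by_cell` data frames.
#' @export
repetition_table <- function(sessions) {
  df <- repetition_indicators(sessions)
  aggregate_choice_metric(df, "repeated", "repetition")
}

#' Psychometric curve of first choices
#'
#' Bins first choices by the right-minus-left expected-value difference
#' (bin edges symmetric about zero) and reports the proportion of right
#' choices per bin with binomial standard errors. Empty bins are reported
#' as missing, not as zero.
#'
#' @param sessions A `horizon_session` or list of them.
#' @param observer An [observer_config()].
#' @param n_bins Number of bins (odd values centre one bin on zero).
#' @param max_abs Half-range of the bin edges; defaults to the largest
#'   absolute observed EV difference.
#' @return A data frame: bin bounds and midpoint, `n`, `p_right`, `se`.
#' @export
psychometric_curve <- function(sessions, observer, n_bins = 11L, max_abs = NULL) {
  sessions <- check_sessions(sessions)
  rows <- lapply(sessions, function(s) {
    do.call(rbind, lapply(seq_len(nrow(s$trials)), function(i) {
      tr <- trial_record(s, i)
      if (nrow(tr$choices) == 0L) return(NULL)
      first <- tr$choices[tr$choices$choice_index == 1L, ]
      ev_l <- belief_state(tr$obs_left, observer)$expected_value
      ev_r <- belief_state(tr$obs_right, observer)$expected_value
      data.frame(ev_diff = ev_r - ev_l, right = first$side == "right")
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(max_abs)) max_abs <- max(abs(df$ev_diff))
  breaks <- seq(-max_abs, max_abs, length.out = n_bins + 1L)
  bin <- cut(df$ev_diff, breaks, include.lowest = TRUE)
  out <- data.frame(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2
  )
  out$n <- as.integer(table(bin))
  p <- tapply(df$right, bin, mean)
  out$p_right <- as.numeric(p)
  out$se <- sqrt(out$p_right * (1 - out$p_right) / out$n)
  out$p_right[out$n == 0L] <- NA_real_
  out$se[out$n == 0L] <- NA_real_
  out
}
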