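oc <- observer_config()

first_session <- function(obs_left, obs_right, horizons, sides, feedback = "partial") {
  trials <- manual_trials(horizons, obs_left, obs_right)
  choices <- data.frame(
    trial_id = seq_along(horizons), choice_index = 1L, side = sides,
    chosen_outcome = 5L,
    unchosen_outcome = if (feedback == "complete") 5L else NA_integer_
  )
  manual_session(trials, choices, feedback)
}

test_that("first-choice regressors follow the stated codings", {
  s <- first_session(
    obs_left = list(c(4L, 6L), c(3L), c(2L, 4L, 6L)),
    obs_right = list(c(4L, 6L), c(5L, 6L, 7L), c(4L)),
    horizons = c(1L, 4L, 1L),
    sides = c("right", "left", "right")
  )
  d <- build_first_choice_design(s, oc)

  # identical observation sets on both sides: EV and U differences vanish
  expect_equal(d$EV[1], 0, tolerance = 1e-12)
  expect_equal(d$U[1], 0, tolerance = 1e-12)

  # horizon coded +1 short / -1 long
  expect_identical(d$horizon, c(1, -1, 1))

  # repetition bias tracks the previous completed trial's last choice
  expect_identical(d$RB, c(0, 1, -1))

  # 3 observations right vs 1 left: right option is less uncertain
  expect_lt(d$U[2], 0)
  # interactions are products with the horizon coding
  expect_equal(d$EVxhorizon, d$EV * d$horizon, tolerance = 1e-12)
  expect_equal(d$Uxhorizon, d$U * d$horizon, tolerance = 1e-12)
  expect_identical(d$response, c(1L, 0L, 1L))

  d_info <- build_first_choice_design(s, oc, variant = "info_count")
  expect_identical(d_info$U, c(0, 2, -2))
  expect_identical(attr(d_info, "variant"), "info_count")
})

test_that("subsequent-choice regressors count choices and split feedback streams", {
  choices <- data.frame(
    trial_id = 1L, choice_index = 1:3,
    side = c("left", "left", "right"),
    chosen_outcome = c(4L, 6L, 7L),
    unchosen_outcome = c(6L, 5L, 4L)
  )
  trials <- manual_trials(4L, list(c(4L, 5L)), list(c(6L, 7L)))
  s_c <- manual_session(trials, choices, "complete")
  d <- build_subsequent_choice_design(s_c, oc)

  # second choice after one left choice
  expect_identical(d$dChosen[1], -1)
  expect_identical(d$RB[1], -1)
  # third choice after two left choices, previous choice left
  expect_identical(d$dChosen[2], -2)
  expect_identical(d$RB[2], -1)
  expect_identical(d$response, c(0L, 1L))
  expect_setequal(attr(d, "regressors"), subsequent_names <- c(
    "SB", "RB", "dChosen", "baselineEV", "dEVchosen", "baselineU",
    "dUchosen", "dEVunchosen", "dUunchosen"))

  # partial feedback: counterfactual columns are exactly zero and leave the schema
  choices_p <- choices
  choices_p$unchosen_outcome <- NA_integer_
  s_p <- manual_session(trials, choices_p, "partial")
  d_p <- build_subsequent_choice_design(s_p, oc)
  expect_identical(d_p$dEVunchosen, c(0, 0))
  expect_identical(d_p$dUunchosen, c(0, 0))
  expect_false(any(c("dEVunchosen", "dUunchosen") %in% attr(d_p, "regressors")))

  # short-horizon-only input is rejected
  s_short <- first_session(list(c(4L, 5L)), list(c(6L, 7L)), 1L, "left")
  expect_error(build_subsequent_choice_design(s_short, oc), "long-horizon")
})

test_that("a chosen outcome equal to the current expected value leaves dEVchosen at zero", {
  # symmetric beliefs around 5: EV is exactly 5, and an outcome of 5 keeps it there
  choices <- data.frame(trial_id = 1L, choice_index = 1:2,
                        side = c("left", "left"),
                        chosen_outcome = c(5L, 5L),
                        unchosen_outcome = NA_integer_)
  trials <- manual_trials(4L, list(c(4L, 6L)), list(c(3L, 7L)))
  d <- build_subsequent_choice_design(manual_session(trials, choices, "partial"), oc)
  expect_lt(abs(d$dEVchosen[1]), 1e-10)
})

test_that("mirroring a session negates the side-difference regressors and flips the response", {
  sessions <- small_experiment()
  s <- sessions[[1]]
  m <- mirror_session(s)

  d <- build_first_choice_design(s, oc)
  dm <- build_first_choice_design(m, oc)
  for (col in c("RB", "EV", "U", "EVxhorizon", "Uxhorizon")) {
    expect_equal(dm[[col]], -d[[col]], tolerance = 1e-10)
  }
  expect_identical(dm$horizon, d$horizon)  # horizon is not a side difference
  expect_identical(dm$SB, d$SB)
  expect_identical(dm$response, 1L - d$response)

  s_c <- sessions[[which(vapply(sessions, `[[`, "", "feedback") == "complete")[1]]]
  d2 <- build_subsequent_choice_design(s_c, oc)
  d2m <- build_subsequent_choice_design(mirror_session(s_c), oc)
  for (col in c("RB", "dChosen", "baselineEV", "dEVchosen", "baselineU",
                "dUchosen", "dEVunchosen", "dUunchosen")) {
    expect_equal(d2m[[col]], -d2[[col]], tolerance = 1e-10)
  }
  expect_identical(d2m$response, 1L - d2$response)
})

test_that("design construction rejects sessions without choices and inconsistent feedback", {
  s <- generate_session(task_config(trials_per_session = 10), seed = 1)
  expect_error(build_first_choice_design(s, oc), "no recorded choices")

  sessions <- small_experiment()
  bad <- sessions[[1]]
  stopifnot(bad$feedback == "partial")
  bad$choices$unchosen_outcome <- 5L
  expect_error(build_first_choice_design(bad, oc),
               "partial-feedback session .* unchosen")
})

test_that("design CSV round trip preserves values and schema", {
  d <- build_first_choice_design(small_experiment()[[1]], oc)
  path <- file.path(tempdir(), "design_rt.csv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_identical(attr(d2, "regressors"), attr(d, "regressors"))
  expect_equal(d2$EV, d$EV, tolerance = 1e-12)
  expect_identical(d2$response, d$response)
})
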