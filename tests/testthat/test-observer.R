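oc <- observer_config()

test_that("discretised likelihood columns are normalised, symmetric and peaked at the mean", {
  expect_true(all(abs(colSums(oc$lik) - 1) < 1e-12))
  expect_equal(outcome_likelihood(3, 5, oc), outcome_likelihood(7, 5, oc))
  lk5 <- vapply(0:10, outcome_likelihood, numeric(1), mu = 5, config = oc)
  expect_identical(which.max(lk5), 6L)  # mode at x = 5
  expect_error(outcome_likelihood(11, 5, oc), "outside the outcome support")
  expect_error(outcome_likelihood(5, 5.013, oc), "not on the mean grid")
})

test_that("posterior over means matches the direct-enumeration oracle", {
  expect_identical(posterior_over_means(integer(), oc), oc$prior)

  p46 <- posterior_over_means(c(4, 6), oc)
  expect_lt(abs(sum(p46 * oc$mean_grid) - 5), 1e-9)
  expect_equal(p46, rev(p46), tolerance = 1e-12)

  set.seed(42)
  for (r in 1:100) {
    obs <- sample(0:10, sample(1:8, 1), replace = TRUE)
    o <- oracle_belief(obs, oc$mean_grid, oc$sigma, oc$outcome_support)
    p <- posterior_over_means(obs, oc)
    expect_lt(abs(sum(p * oc$mean_grid) - sum(o$posterior * oc$mean_grid)), 1e-8)
    expect_lt(max(abs(p - o$posterior)), 1e-10)
  }
})

test_that("posterior is invariant under reordering of observations", {
  set.seed(3)
  for (r in 1:20) {
    obs <- sample(0:10, 6, replace = TRUE)
    expect_identical(posterior_over_means(obs, oc),
                     posterior_over_means(sample(obs), oc))
  }
})

test_that("predictive distribution mixes likelihoods correctly", {
  # point-mass posterior degenerates to that mean's likelihood column
  j <- which(abs(oc$mean_grid - 6.5) < 1e-9)
  point <- replace(numeric(length(oc$mean_grid)), j, 1)
  expect_equal(predictive_next_outcome(point, oc), oc$lik[, j],
               tolerance = 1e-12)

  # uniform posterior on the symmetric grid gives a symmetric predictive
  pred <- predictive_next_outcome(oc$prior, oc)
  expect_equal(pred, rev(pred), tolerance = 1e-12)
  expect_lt(abs(sum(pred) - 1), 1e-10)

  set.seed(9)
  for (r in 1:20) {
    obs <- sample(0:10, 4, replace = TRUE)
    pred <- predictive_next_outcome(posterior_over_means(obs, oc), oc)
    expect_lt(abs(sum(pred) - 1), 1e-10)
  }
})

test_that("belief summaries compute the predictive mean and variance", {
  point7 <- replace(numeric(11), 8, 1)
  s <- belief_summary(point7, oc)
  expect_identical(s$expected_value, 7)
  expect_identical(s$uncertainty, 0)

  unif <- rep(1 / 11, 11)
  s <- belief_summary(unif, oc)
  expect_equal(s$expected_value, 5, tolerance = 1e-12)
  expect_equal(s$uncertainty, 10, tolerance = 1e-12)  # sum((x-5)^2)/11 = 110/11

  # uncertainty shrinks as observations accrue at fixed sample mean
  expect_lt(belief_state(c(5, 5, 5), oc)$uncertainty,
            belief_state(5, oc)$uncertainty)
})

test_that("dense-grid predictive variance tracks the conjugate closed form", {
  fine <- observer_config(mean_grid = seq(0, 10, by = 0.01))
  for (n in c(1, 2, 5, 10)) {
    obs <- rep(5, n)
    o <- oracle_belief(obs, fine$mean_grid, fine$sigma, fine$outcome_support)
    u <- belief_state(obs, fine)$uncertainty
    expect_lt(abs(u - o$u), 1e-8)
    closed <- fine$sigma^2 * (1 + 1 / n)
    # discretisation (integer outcomes, bounded support) shifts the variance
    # by < 5% of the closed form at sigma = 1.5
    expect_lt(abs(u - closed) / closed, 0.05)
  }
})

test_that("posterior mean is consistent for in-grid generative means", {
  cfg <- task_config(trials_per_session = 10)
  set.seed(123)
  obs <- sample_outcome(5, cfg, n = 200)
  p <- posterior_over_means(obs, oc)
  expect_lt(abs(sum(p * oc$mean_grid) - 5), 0.1)
})

test_that("belief trajectories separate the three information streams correctly", {
  choices <- data.frame(
    trial_id = 1L, choice_index = 1:3,
    side = c("left", "right", "left"),
    chosen_outcome = c(4L, 7L, 5L),
    unchosen_outcome = c(6L, 3L, 8L)
  )
  trial <- list(obs_left = c(4L, 5L), obs_right = c(6L, 7L), choices = choices)

  bt_c <- belief_trajectory(trial, "complete", oc)
  first <- bt_c[bt_c$choice_index == 1, ]
  for (side in c("left", "right")) {
    evs <- first$EV[first$side == side]
    expect_true(all(abs(evs - evs[1]) < 1e-12))  # all streams equal pre-feedback
  }

  # after one left choice the right option's full stream has one extra
  # (counterfactual) observation relative to its chosen-only stream
  second <- bt_c[bt_c$choice_index == 2 & bt_c$side == "right", ]
  expect_identical(second$n_obs[second$stream == "full"],
                   second$n_obs[second$stream == "chosen"] + 1L)
  # beliefs at choice k only use feedback revealed strictly before k
  third <- bt_c[bt_c$choice_index == 3, ]
  expect_identical(sum(third$n_obs[third$stream == "full"]), 4L + 2L * 2L)

  trial_p <- trial
  trial_p$choices$unchosen_outcome <- NA_integer_
  bt_p <- belief_trajectory(trial_p, "partial", oc)
  chosen <- bt_p[bt_p$stream == "chosen", c("EV", "U", "n_obs")]
  full <- bt_p[bt_p$stream == "full", c("EV", "U", "n_obs")]
  expect_identical(chosen$EV, full$EV)
  expect_identical(chosen$U, full$U)
  expect_identical(chosen$n_obs, full$n_obs)

  bad <- trial
  bad$obs_left <- c(4L, 12L)
  expect_error(belief_trajectory(bad, "complete", oc), "outside the outcome support")
})
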