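oc <- observer_config()

test_that("session t test matches the textbook closed form", {
  res <- session_ttest(c(0.6, 0.7, 0.8), 0.5)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)  # 0.2 / (0.1 / sqrt(3))
  expect_identical(res$dof, 2L)
  expect_false(res$degenerate)

  # dof shape: n sessions give n - 1 degrees of freedom
  set.seed(1)
  res41 <- session_ttest(runif(41, 0.55, 0.95), 0.5)
  expect_identical(res41$dof, 40L)

  # degenerate inputs are reported explicitly, not errored
  flat <- session_ttest(rep(0.5, 4), 0.5)
  expect_identical(flat$t, 0)
  expect_identical(flat$p, 1)
  expect_true(flat$degenerate)
  above <- session_ttest(rep(0.7, 4), 0.5)
  expect_identical(above$t, Inf)
  expect_identical(above$p, 0)
  expect_error(session_ttest(0.6, 0.5), "at least 2 sessions")
})

test_that("accuracy is 1 for a greedy agent and near chance for a coin flipper", {
  cfg <- task_config(trials_per_session = 30)
  greedy <- agent_params(
    first = c(EV = 1e6),
    subsequent = c(baselineEV = 1e6, dEVchosen = 1e6, dEVunchosen = 1e6))
  gs <- lapply(1:2, function(i) {
    simulate_agent(generate_session(cfg, seed = i, session_id = paste0("g", i)),
                   greedy, oc, seed = 10 + i)
  })
  acc <- accuracy_table(gs, oc)
  expect_true(all(acc$by_cell$accuracy == 1))

  coin <- agent_params()
  cfg_big <- task_config(trials_per_session = 250)
  cs <- lapply(1:8, function(i) {
    simulate_agent(generate_session(cfg_big, seed = 100 + i,
                                    session_id = paste0("c", i)),
                   coin, oc, seed = 200 + i)
  })
  scored <- horizontask:::score_choices(cs, oc)
  scored <- scored[!is.na(scored$correct), ]
  n <- nrow(scored)
  expect_gt(n, 4000)
  expect_lt(abs(mean(scored$correct) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("repetition rates hit the sticky and side-blind limits", {
  cfg <- task_config(trials_per_session = 30)
  sticky <- agent_params(first = c(EV = 1), subsequent = c(RB = 60))
  ss <- lapply(1:2, function(i) {
    simulate_agent(generate_session(cfg, seed = 20 + i,
                                    session_id = paste0("s", i)),
                   sticky, oc, seed = 30 + i)
  })
  rep_tab <- repetition_table(ss)
  expect_true(all(rep_tab$by_cell$repetition == 1))

  coin <- agent_params()
  cfg_big <- task_config(trials_per_session = 200)
  cs <- lapply(1:6, function(i) {
    simulate_agent(generate_session(cfg_big, seed = 300 + i,
                                    session_id = paste0("r", i)),
                   coin, oc, seed = 400 + i)
  })
  ind <- horizontask:::repetition_indicators(cs)
  n <- nrow(ind)
  expect_lt(abs(mean(ind$repeated) - 0.5), 3 * sqrt(0.25 / n))
})

# Sessions whose per-choice correctness frequencies are fixed by
# construction: in every long trial the right option is unambiguously
# better (observations and outcomes keep its EV strictly higher), so a
# choice is correct exactly when it is "right". `n_correct[k]` sets how
# many of the 10 long trials are correct at choice k.
trend_session <- function(n_correct, session_id) {
  n_trials <- 10L
  trials <- manual_trials(rep(4L, n_trials),
                          obs_left = rep(list(c(3L, 3L)), n_trials),
                          obs_right = rep(list(c(7L, 7L)), n_trials))
  choices <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
    side <- ifelse(tr <= n_correct, "right", "left")[rep(1, 4)]
    # chosen outcomes preserve the right option's dominance
    data.frame(trial_id = tr, choice_index = 1:4, side = side,
               chosen_outcome = ifelse(side == "right", 7L, 3L),
               unchosen_outcome = NA_integer_)
  }))
  cfg <- task_config(trials_per_session = 10, block_length = 5,
                     horizon_short = 1, horizon_long = 4)
  manual_session(trials, choices, "partial", config = cfg,
                 session_id = session_id)
}

test_that("within-horizon trends detect improvement and report degenerate sessions", {
  # 40 sessions with correctness rising across choices 1-4 by construction
  rising <- lapply(1:40, function(i) {
    base <- 4L + i %% 3L  # jitter so slopes vary across sessions
    s <- trend_session(base, sprintf("up%02d", i))
    s$choices$side <- unlist(lapply(split(s$choices, s$choices$trial_id), function(tr) {
      ifelse(tr$choice_index <= 2, tr$side,
             ifelse(tr$trial_id <= min(base + 2L + tr$trial_id %% 2L, 10L),
                    "right", "left"))
    }))
    s$choices$chosen_outcome <- ifelse(s$choices$side == "right", 7L, 3L)
    s
  })
  tr <- within_horizon_trend(rising, "accuracy", oc)
  expect_identical(nrow(tr$slopes), 40L)
  expect_gt(mean(tr$slopes$slope), 0)
  expect_gt(tr$ttest$t, 0)
  expect_lt(tr$ttest$p, 0.001)
  expect_identical(tr$ttest$dof, 39L)

  # reversing the correctness pattern in time negates every slope exactly
  falling <- lapply(rising, function(s) {
    s$choices$side <- unlist(lapply(split(s$choices, s$choices$trial_id),
                                    function(tr) rev(tr$side)))
    s$choices$chosen_outcome <- ifelse(s$choices$side == "right", 7L, 3L)
    s$session_id <- paste0(s$session_id, "rev")
    s
  })
  tf <- within_horizon_trend(falling, "accuracy", oc)
  expect_equal(tf$slopes$slope, -tr$slopes$slope, tolerance = 1e-10)

  # constant quantity: every session dropped, reported explicitly
  greedy <- agent_params(
    first = c(EV = 1e6),
    subsequent = c(baselineEV = 1e6, dEVchosen = 1e6, dEVunchosen = 1e6))
  gs <- lapply(1:2, function(i) {
    simulate_agent(generate_session(task_config(trials_per_session = 20),
                                    seed = i, session_id = paste0("g", i)),
                   greedy, oc, seed = 10 + i)
  })
  tg <- suppressWarnings(within_horizon_trend(gs, "accuracy", oc))
  expect_identical(nrow(tg$slopes), 0L)
  expect_null(tg$ttest)
  expect_identical(sort(tg$dropped), c("g1", "g2"))
})

test_that("psychometric curves are monotone, antisymmetric and recover the slope", {
  logistic <- agent_params(first = c(EV = 1))
  cfg <- task_config(trials_per_session = 500)
  ls <- lapply(1:6, function(i) {
    simulate_agent(generate_session(cfg, seed = 700 + i,
                                    session_id = paste0("p", i)),
                   logistic, oc, seed = 800 + i)
  })
  curve <- psychometric_curve(ls, oc, n_bins = 9)
  ok <- !is.na(curve$p_right)
  # monotone non-decreasing within sampling error: regression slope positive
  expect_gt(coef(lm(p_right ~ bin_mid, data = curve[ok, ]))[2], 0)

  # mirror-symmetric dataset: P(bin) = 1 - P(-bin) exactly
  both <- c(ls[1:2], lapply(ls[1:2], mirror_session))
  sym <- psychometric_curve(both, oc, n_bins = 9)
  expect_equal(sym$p_right, rev(1 - sym$p_right), tolerance = 1e-12)

  # logistic-slope recovery from the raw first choices
  first <- do.call(rbind, lapply(ls, function(s) {
    d <- build_first_choice_design(s, oc)
    data.frame(ev = d$EV, right = d$response)
  }))
  slope <- coef(glm(right ~ ev, family = binomial(), data = first))["ev"]
  expect_lt(abs(slope - 1), 0.15)
})
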