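test_that("one-sided posterior-count p-values count draws on the null side", {
  expect_equal(as.numeric(one_sided_p(c(-1, 1, 1, 1), "greater")), 0.25)
  expect_equal(as.numeric(one_sided_p(c(-1, 1, 1, 1), "smaller")), 0.75)

  # draws exactly at zero count against the hypothesis (conservative)
  expect_equal(as.numeric(one_sided_p(c(0, 1), "greater")), 0.5)
  expect_equal(as.numeric(one_sided_p(c(0, -1), "smaller")), 0.5)

  set.seed(1)
  sym <- rnorm(20000)
  expect_lt(abs(one_sided_p(sym, "greater") - 0.5), 0.02)

  p <- one_sided_p(rep(1, 12000), "greater")
  expect_identical(as.numeric(p), 0)
  expect_identical(format_posterior_p(p), "<1/12000")
  expect_error(one_sided_p(numeric(), "greater"), "non-empty")
})

fake_fit <- function() {
  set.seed(10)
  cells <- expand.grid(animal = c("m1", "m2"),
                       condition = c("complete", "partial"),
                       stringsAsFactors = FALSE)
  mu <- array(rnorm(200 * 2 * 4), dim = c(200, 2, 4),
              dimnames = list(NULL, c("SB", "EV"), NULL))
  # identical draws for the two animals within each condition
  mu[, , 2] <- mu[, , 1]
  mu[, , 4] <- mu[, , 3]
  structure(list(mu = mu, sigma = NULL, coefficients = c("SB", "EV"),
                 animals = c("m1", "m2"),
                 conditions = c("complete", "partial"),
                 cells = cells, n_draws = 200,
                 hierarchical = FALSE, flagged = FALSE,
                 diagnostics = data.frame()),
            class = "horizon_fit")
}

test_that("contrasts weight cells and average over unnamed dimensions", {
  fit <- fake_fit()
  # identity weights on one cell return that cell's draws unchanged
  one <- contrast_draws(fit, data.frame(coefficient = "EV", animal = "m1",
                                        condition = "complete", weight = 1))
  expect_equal(one, fit$mu[, "EV", 1])

  # averaging identical per-animal draws returns the same draws
  avg <- group_draws(fit, "EV", condition = "complete")
  expect_equal(avg, fit$mu[, "EV", 1])

  # complete - partial difference
  diffd <- contrast_draws(fit, data.frame(
    coefficient = "EV", condition = c("complete", "partial"),
    weight = c(1, -1)))
  expect_equal(diffd, fit$mu[, "EV", 1] - fit$mu[, "EV", 3])

  expect_error(contrast_draws(fit, data.frame(coefficient = "nope", weight = 1)),
               "unknown coefficient")
  expect_error(contrast_draws(fit, data.frame(coefficient = "EV", weight = 1,
                                              animal = "m9")), "no cell matches")
})

test_that("the no-hierarchy reduction matches a maximum-likelihood logistic fit", {
  set.seed(21)
  n <- 800
  X <- cbind(SB = 1, EV = rnorm(n, 0, 1.5), RB = sample(c(-1, 1), n, TRUE))
  beta <- c(0.3, 0.9, -0.4)
  y <- rbinom(n, 1, plogis(X %*% beta))
  design <- data.frame(animal_id = "m1", session_id = "s1",
                       feedback = "partial", X, response = y)

  fit <- suppressMessages(fit_choice_model(
    design, fit_config(n_chains = 2, n_warmup = 400, n_samples = 600, seed = 4),
    regressors = c("SB", "EV", "RB")))

  ml <- glm(y ~ 0 + X, family = binomial())
  post_mean <- apply(fit$mu[, , 1], 2, mean)
  expect_lt(max(abs(post_mean - coef(ml))), 0.05)
  expect_identical(fit$n_draws, fit$config$n_chains * fit$config$n_samples)
})

test_that("non-identifiable designs are rejected with the offending column named", {
  set.seed(2)
  n <- 100
  design <- data.frame(animal_id = "m1", session_id = "s1", feedback = "partial",
                       SB = 1, EV = rnorm(n), U = 0,
                       response = rbinom(n, 1, 0.5))
  expect_error(
    suppressMessages(fit_choice_model(design, fit_config(n_chains = 2),
                                      regressors = c("SB", "EV", "U"))),
    "`U` is constant")

  sep <- data.frame(animal_id = "m1", session_id = "s1", feedback = "partial",
                    SB = 1, EV = c(rnorm(50, -4), rnorm(50, 4)))
  sep$response <- as.integer(sep$EV > 0)
  expect_error(
    suppressMessages(fit_choice_model(sep, fit_config(n_chains = 2),
                                      regressors = c("SB", "EV"))),
    "separated")
})

test_that("hierarchical fits expose diagnostics and are label-invariant", {
  sessions <- small_experiment()
  oc <- observer_config()
  d <- build_first_choice_design(sessions, oc)
  cfg <- fit_config(n_chains = 2, n_warmup = 150, n_samples = 150, seed = 11)
  fit <- fit_choice_model(d, cfg)

  expect_identical(fit$n_draws, 300L)
  expect_true(all(c("rhat", "ess", "flagged") %in% names(fit$diagnostics)))
  # split-Rhat reported for every monitored parameter
  n_mu <- length(fit$coefficients) * nrow(fit$cells)
  n_sg <- length(fit$coefficients) * length(fit$animals)
  expect_identical(nrow(fit$diagnostics), n_mu + n_sg)

  s <- summary(fit)
  expect_true(all(abs(s$p_greater + s$p_smaller - 1) <= 1 / fit$n_draws + 1e-12))

  # renaming animals (order-preserving) must not change any estimate
  d2 <- d
  d2$animal_id <- sub("^m", "monkey", d2$animal_id)
  fit2 <- fit_choice_model(d2, cfg)
  expect_equal(unname(fit2$mu), unname(fit$mu), tolerance = 1e-12)
})
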