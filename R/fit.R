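#' MCMC settings for the hierarchical choice model
#'
#' Defaults mirror the analysis scale of 12 chains with 1,000 retained
#' iterations each after 1,000 warm-up samples. For quick runs use fewer
#' chains and iterations, e.g. `fit_config(n_chains = 2, n_warmup = 200,
#' n_samples = 300)`.
#'
#' @param n_chains Number of MCMC chains (>= 2 for split-R-hat).
#' @param n_warmup Warm-up iterations per chain (split between sampler
#'   adaptation and burn-in).
#' @param n_samples Retained iterations per chain.
#' @param prior_scale,prior_df Scale and degrees of freedom of the
#'   Student-t prior on fixed effects and of the half-Student-t prior on
#'   random-effect SDs (weakly informative; inference targets the
#'   likelihood-dominated regime).
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_chains = 12L, n_warmup = 1000L, n_samples = 1000L,
                       prior_scale = 2.5, prior_df = 3, seed = 1L) {
  if (!is_count(n_chains) || n_chains < 2) stopf("`n_chains` must be an integer >= 2")
  if (!is_count(n_warmup) || !is_count(n_samples)) {
    stopf("`n_warmup` and `n_samples` must be positive integers")
  }
  structure(
    list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
         n_samples = as.integer(n_samples),
         prior_scale = prior_scale, prior_df = prior_df,
         seed = as.integer(seed)),
    class = "fit_config"
  )
}

jags_model_hier <- "
model {
  for (i in 1:N) {
    logit(p[i]) <- inprod(X[i, ], b[sess[i], ])
    y[i] ~ dbern(p[i])
  }
  for (s in 1:S) {
    for (k in 1:K) {
      b[s, k] ~ dnorm(mu[cell[s], k], tau[animal[s], k])
    }
  }
  for (c in 1:C) {
    for (k in 1:K) { mu[c, k] ~ dt(0, prior_prec, prior_df) }
  }
  for (a in 1:A) {
    for (k in 1:K) {
      sg[a, k] ~ dt(0, prior_prec, prior_df) T(0, )
      tau[a, k] <- pow(sg[a, k], -2)
    }
  }
}"

jags_model_flat <- "
model {
  for (i in 1:N) {
    logit(p[i]) <- inprod(X[i, ], mu[cell_obs[i], ])
    y[i] ~ dbern(p[i])
  }
  for (c in 1:C) {
    for (k in 1:K) { mu[c, k] ~ dt(0, prior_prec, prior_df) }
  }
}"

check_design_identifiable <- function(X, design, regressors) {
  # Constant columns (other than the side-bias intercept) carry no
  # information and break the sampler.
  for (k in setdiff(regressors, "SB")) {
    v <- X[, k]
    if (stats::var(v) == 0) {
      # Counterfactual columns are structurally zero within partial-feedback
      # cells; they are only rejected if constant across the whole design.
      stopf("regressor `%s` is constant across the design; drop it or vary the input", k)
    }
  }
  # Cheap perfect-separation screen on the pooled design.
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, design$response, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  if (sep && max(abs(fit$coefficients), na.rm = TRUE) > 10) {
    worst <- names(which.max(abs(fit$coefficients)))
    stopf("design appears perfectly separated (dominant column `%s`)",
          regressors[which.max(abs(fit$coefficients))] %||% worst)
  }
  invisible(TRUE)
}

#' Fit the hierarchical Bayesian logistic choice model
#'
#' Bernoulli-logit regression of the binary response on the design's
#' regressor schema. Every coefficient is a fixed effect per animal x
#' feedback-condition cell; session-level coefficient vectors are random
#' effects drawn from per-animal, per-coefficient Gaussians centred on the
#' cell fixed effects (independent across coefficients). Sampling is by
#' MCMC (JAGS); the backend is a contract, not part of the model. When the
#' design holds a single session (or any cell has fewer than two sessions),
#' the session hierarchy is dropped and the cell fixed effects are fit
#' directly.
#'
#' @param design A design data frame from [build_first_choice_design()] or
#'   [build_subsequent_choice_design()] (or any data frame with a binary
#'   `response`, grouping columns `animal_id`, `session_id`, `feedback`,
#'   and a `regressors` attribute or `regressors` argument).
#' @param config A [fit_config()].
#' @param regressors Optional character vector of regressor columns,
#'   overriding `attr(design, "regressors")`.
#' @param hierarchical Fit session random effects (default) or the flat
#'   cell-level model.
#' @return An object of class `horizon_fit` holding posterior draws
#'   `mu[draw, coefficient, cell]` (cells are animal x condition),
#'   random-effect SD draws `sigma[draw, coefficient, animal]` (when
#'   hierarchical), per-parameter split-R-hat and effective sample sizes,
#'   and a `flagged` indicator for R-hat > 1.05 or ESS < 400.
#' @export
fit_choice_model <- function(design, config = fit_config(),
                             regressors = attr(design, "regressors"),
                             hierarchical = TRUE) {
  stopifnot(inherits(config, "fit_config"))
  if (is.null(regressors)) {
    stopf("no regressor schema: pass `regressors` or a design built by the package")
  }
  missing_cols <- setdiff(c(regressors, "response", "animal_id", "session_id",
                            "feedback"), names(design))
  if (length(missing_cols)) {
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(design[, regressors, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stopf("design contains non-finite regressor values")
  y <- as.integer(design$response)
  if (!all(y %in% c(0L, 1L))) stopf("`response` must be binary 0/1")
  check_design_identifiable(X, design, regressors)

  sess_key <- paste(design$animal_id, design$feedback, design$session_id, sep = "\r")
  sess_f <- factor(sess_key, levels = unique(sess_key))
  sess_meta <- design[!duplicated(sess_key), c("animal_id", "feedback", "session_id")]
  animals <- sort(unique(design$animal_id))
  conditions <- sort(unique(design$feedback))
  cell_key <- paste(sess_meta$animal_id, sess_meta$feedback, sep = "\r")
  cells <- expand.grid(animal = animals, condition = conditions,
                       stringsAsFactors = FALSE)
  cells$key <- paste(cells$animal, cells$condition, sep = "\r")
  cells <- cells[cells$key %in% cell_key, , drop = FALSE]
  rownames(cells) <- NULL
  cell_of_sess <- match(cell_key, cells$key)
  animal_of_sess <- match(sess_meta$animal_id, animals)

  min_sessions <- min(table(cell_of_sess))
  if (hierarchical && min_sessions < 2L) {
    message("fewer than 2 sessions in some animal x condition cell; ",
            "dropping the session hierarchy")
    hierarchical <- FALSE
  }

  K <- ncol(X)
  dat <- list(N = nrow(X), K = K, C = nrow(cells), y = y, X = X,
              prior_prec = 1 / config$prior_scale^2, prior_df = config$prior_df)
  if (hierarchical) {
    dat$S <- nlevels(sess_f)
    dat$sess <- as.integer(sess_f)
    dat$cell <- cell_of_sess
    dat$animal <- animal_of_sess
    dat$A <- length(animals)
    model_string <- jags_model_hier
    monitors <- c("mu", "sg")
  } else {
    dat$cell_obs <- cell_of_sess[as.integer(sess_f)]
    model_string <- jags_model_flat
    monitors <- "mu"
  }

  chain_seeds <- derive_seeds(config$seed, config$n_chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
  n_adapt <- max(100L, config$n_warmup %/% 2L)
  n_burn <- max(0L, config$n_warmup - n_adapt)
  jm <- rjags::jags.model(textConnection(model_string), data = dat,
                          inits = inits, n.chains = config$n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) stats::update(jm, n.iter = n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = monitors,
                                 n.iter = config$n_samples,
                                 progress.bar = "none")

  coef_names <- colnames(X)
  vn <- coda::varnames(samples)
  pick <- function(pattern) vn[grepl(pattern, vn)]
  flat <- do.call(rbind, lapply(samples, as.matrix))

  mu_names <- pick("^mu\\[")
  mu <- array(NA_real_, dim = c(nrow(flat), K, nrow(cells)),
              dimnames = list(NULL, coef_names,
                              paste(cells$animal, cells$condition, sep = ":")))
  for (nm in mu_names) {
    ij <- as.integer(strsplit(gsub("mu\\[|\\]", "", nm), ",")[[1]])
    mu[, ij[2], ij[1]] <- flat[, nm]
  }
  sigma <- NULL
  if (hierarchical) {
    sg_names <- pick("^sg\\[")
    sigma <- array(NA_real_, dim = c(nrow(flat), K, length(animals)),
                   dimnames = list(NULL, coef_names, animals))
    for (nm in sg_names) {
      ij <- as.integer(strsplit(gsub("sg\\[|\\]", "", nm), ",")[[1]])
      sigma[, ij[2], ij[1]] <- flat[, nm]
    }
  }

  diagnostics <- fit_diagnostics(samples)
  fit <- structure(
    list(mu = mu, sigma = sigma,
         coefficients = coef_names, animals = animals, conditions = conditions,
         cells = cells[, c("animal", "condition")],
         n_draws = nrow(flat), config = config,
         hierarchical = hierarchical,
         diagnostics = diagnostics,
         flagged = any(diagnostics$flagged),
         regressors = regressors,
         variant = attr(design, "variant") %||% "uncertainty"),
    class = "horizon_fit"
  )
  stopifnot(fit$n_draws == config$n_chains * config$n_samples)
  fit
}

# Split-R-hat (each chain split in half) and effective sample size per
# monitored parameter.
fit_diagnostics <- function(samples) {
  vn <- coda::varnames(samples)
  ess <- coda::effectiveSize(samples)
  rhat <- vapply(vn, function(nm) {
    chains <- lapply(samples, function(ch) as.numeric(ch[, nm]))
    split_rhat(chains)
  }, numeric(1))
  data.frame(parameter = vn, rhat = unname(rhat), ess = unname(ess[vn]),
             flagged = unname(rhat > 1.05 | ess[vn] < 400))
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[seq.int(n + 1L, 2L * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.horizon_fit <- function(x, ...) {
  cat(sprintf("Hierarchical choice-model fit (%s): %d coefficients, %d cells, %d draws\n",
              if (x$hierarchical) "session random effects" else "flat",
              length(x$coefficients), nrow(x$cells), x$n_draws))
  if (x$flagged) {
    bad <- x$diagnostics[x$diagnostics$flagged, ]
    cat(sprintf("  CONVERGENCE FLAG: %d parameter(s) with split-Rhat > 1.05 or ESS < 400\n",
                nrow(bad)))
    cat(sprintf("  worst Rhat %.3f, smallest ESS %.0f\n",
                max(bad$rhat), min(bad$ess)))
  } else {
    cat("  all parameters pass split-Rhat <= 1.05 and ESS >= 400\n")
  }
  invisible(x)
}

#' Posterior summary of a choice-model fit
#'
#' @param object A `horizon_fit`.
#' @param ... Unused.
#' @return A data frame with one row per (coefficient, animal, condition):
#'   posterior mean, SD, 2.5/97.5 percent quantiles, one-sided
#'   posterior-count p-values in both directions, split-R-hat and ESS.
#' @export
summary.horizon_fit <- function(object, ...) {
  rows <- list()
  for (ci in seq_len(nrow(object$cells))) {
    for (k in seq_along(object$coefficients)) {
      d <- object$mu[, k, ci]
      par <- sprintf("mu[%d,%d]", ci, k)
      di <- object$diagnostics[object$diagnostics$parameter == par, ]
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = object$coefficients[k],
        animal = object$cells$animal[ci],
        condition = object$cells$condition[ci],
        mean = mean(d), sd = stats::sd(d),
        q2.5 = unname(stats::quantile(d, 0.025)),
        q97.5 = unname(stats::quantile(d, 0.975)),
        p_greater = one_sided_p(d, "greater"),
        p_smaller = one_sided_p(d, "smaller"),
        rhat = if (nrow(di)) di$rhat else NA_real_,
        ess = if (nrow(di)) di$ess else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided posterior-count p-value
#'
#' The fraction of posterior draws on the non-hypothesised side of zero:
#' for `direction = "greater"` the fraction of draws <= 0, for
#' `direction = "smaller"` the fraction >= 0. Draws exactly at zero count
#' on the null side (conservative). When no draw crosses, the resolution
#' floor is 1/N; [format_posterior_p()] renders such values as `"<1/N"`.
#'
#' @param draws Numeric vector of posterior draws.
#' @param direction Hypothesised sign of the effect.
#' @return A probability, with the draw count attached as attribute
#'   `n_draws`.
#' @export
#' @examples
#' one_sided_p(c(-1, 1, 1, 1), "greater")  # 0.25
one_sided_p <- function(draws, direction = c("greater", "smaller")) {
  direction <- match.arg(direction)
  if (length(draws) == 0L) stopf("`draws` must be non-empty")
  p <- if (direction == "greater") mean(draws <= 0) else mean(draws >= 0)
  structure(p, n_draws = length(draws))
}

#' Format a posterior-count p-value for reporting
#'
#' @param p Output of [one_sided_p()].
#' @param n_draws Draw count (taken from the attribute when present).
#' @return A string, `"<1/N"` when zero draws crossed zero.
#' @export
format_posterior_p <- function(p, n_draws = attr(p, "n_draws")) {
  if (!is.null(n_draws) && p == 0) sprintf("<1/%d", n_draws) else format(as.numeric(p))
}

#' Linear contrast over animal x condition cells
#'
#' Computes a per-draw weighted combination of cell-level coefficient
#' draws. Each row of `spec` names a coefficient and a weight; `animal`
#' and/or `condition` may be `NA`, meaning the weight is spread equally
#' over the matching cells (the paper-style average across animals and/or
#' conditions). Supports the headline contrasts: complete minus partial on
#' the expected-value weight, the short-minus-long gap (twice the
#' EV-by-horizon interaction under the +1/-1 coding), and condition
#' differences in repetition bias.
#'
#' @param fit A `horizon_fit`.
#' @param spec Data frame with columns `coefficient`, `weight` and
#'   optionally `animal`, `condition`.
#' @return Numeric vector of contrast draws.
#' @export
#' @examples
#' \dontrun{
#' gap <- contrast_draws(fit, data.frame(
#'   coefficient = "EV", condition = c("complete", "partial"),
#'   weight = c(1, -1)))
#' one_sided_p(gap, "greater")
#' }
contrast_draws <- function(fit, spec) {
  stopifnot(inherits(fit, "horizon_fit"), is.data.frame(spec))
  if (!all(c("coefficient", "weight") %in% names(spec))) {
    stopf("`spec` needs columns `coefficient` and `weight`")
  }
  if (is.null(spec$animal)) spec$animal <- NA_character_
  if (is.null(spec$condition)) spec$condition <- NA_character_
  out <- numeric(fit$n_draws)
  for (i in seq_len(nrow(spec))) {
    k <- match(spec$coefficient[i], fit$coefficients)
    if (is.na(k)) stopf("unknown coefficient `%s`", spec$coefficient[i])
    sel <- rep(TRUE, nrow(fit$cells))
    if (!is.na(spec$animal[i])) sel <- sel & fit$cells$animal == spec$animal[i]
    if (!is.na(spec$condition[i])) {
      sel <- sel & fit$cells$condition == spec$condition[i]
    }
    if (!any(sel)) {
      stopf("no cell matches animal=%s, condition=%s",
            spec$animal[i], spec$condition[i])
    }
    w <- spec$weight[i] / sum(sel)
    for (ci in which(sel)) out <- out + w * fit$mu[, k, ci]
  }
  out
}

#' Group-level draws of one coefficient
#'
#' Convenience wrapper around [contrast_draws()]: the equal-weight average
#' of a coefficient's cell draws over animals (and over conditions unless
#' one is named).
#'
#' @param fit A `horizon_fit`.
#' @param coefficient Coefficient name.
#' @param condition Optional condition to restrict to.
#' @param animal Optional animal to restrict to.
#' @return Numeric vector of draws.
#' @export
group_draws <- function(fit, coefficient, condition = NULL, animal = NULL) {
  contrast_draws(fit, data.frame(
    coefficient = coefficient, weight = 1,
    animal = animal %||% NA_character_,
    condition = condition %||% NA_character_
  ))
}

#' Persist a fit as a draws table and JSON summary
#'
#' @param fit A `horizon_fit`.
#' @param prefix File-path prefix; writes `<prefix>_draws.csv` (one row
#'   per draw, one column per coefficient:cell) and `<prefix>_summary.json`.
#' @return `prefix`, invisibly.
#' @export
write_fit <- function(fit, prefix) {
  draws <- do.call(cbind, lapply(seq_len(nrow(fit$cells)), function(ci) {
    m <- fit$mu[, , ci, drop = FALSE][, , 1]
    colnames(m) <- paste(fit$coefficients, fit$cells$animal[ci],
                         fit$cells$condition[ci], sep = ":")
    m
  }))
  utils::write.csv(as.data.frame(draws), paste0(prefix, "_draws.csv"),
                   row.names = FALSE)
  s <- summary(fit)
  jsonlite::write_json(
    list(summary = s, flagged = fit$flagged,
         n_draws = fit$n_draws, hierarchical = fit$hierarchical),
    paste0(prefix, "_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(prefix)
}
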