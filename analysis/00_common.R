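# Shared settings for the analysis scripts. Each numbered script can be run
# from the repository root with Rscript and writes its tables to results/.
library(horizontask)

RESULTS_DIR <- "results"
if (!dir.exists(RESULTS_DIR)) dir.create(RESULTS_DIR, recursive = TRUE)

SEED <- 20260928L

# Study-scale generative settings: 3 animals, 13 sessions per feedback
# condition, 100-trial sessions.
study_task <- task_config(trials_per_session = 100)
study_observer <- observer_config()
ANIMALS <- paste0("m", 1:3)
SESSIONS_PER_CONDITION <- 13L

# A behaviourally plausible agent: positive reliance on expected value
# (stronger under complete feedback), mild risk aversion, repetition bias
# (stronger under partial feedback), and a short/long EV gap in the partial
# condition only -- the strategic-exploration pattern.
study_agent <- function(animal_id, feedback) {
  partial <- identical(feedback, "partial")
  agent_params(
    first = c(SB = 0.1, RB = if (partial) 0.3 else 0.15, horizon = 0.1,
              EV = if (partial) 0.8 else 1.2, U = -0.15,
              EVxhorizon = if (partial) 0.3 else 0, Uxhorizon = 0),
    subsequent = c(SB = 0.1, RB = if (partial) 0.6 else 0.3, dChosen = 0.2,
                   baselineEV = if (partial) 0.5 else 0.7, dEVchosen = 0.5,
                   baselineU = -0.1, dUchosen = 0,
                   dEVunchosen = if (partial) 0 else 0.4, dUunchosen = 0)
  )
}

# Reduced-scale MCMC used throughout the scripts; raise to
# fit_config() defaults (12 chains x 1,000) for publication-scale runs.
script_fit_config <- function(seed) {
  fit_config(n_chains = 2L, n_warmup = 300L, n_samples = 300L, seed = seed)
}
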