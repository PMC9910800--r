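#!/usr/bin/env Rscript
# Fit the hierarchical logistic model of second-to-fourth choices in the
# long horizon, separating baseline expectations from chosen-feedback and
# counterfactual updates. Writes results/fit_subsequent_* and
# results/subsequent_choice_contrasts.json.
source("analysis/00_common.R")

sessions <- read_sessions(file.path(RESULTS_DIR, "sessions"))
design <- build_subsequent_choice_design(sessions, study_observer)
message("Subsequent-choice design: ", nrow(design), " rows; ",
        "counterfactual columns are structural zeros on partial rows: ",
        all(design$dEVunchosen[design$feedback == "partial"] == 0))

fit <- fit_choice_model(design, script_fit_config(SEED + 2L))
print(fit)
message("note: the counterfactual coefficients of partial-feedback cells are ",
        "prior-dominated (their design columns are structural zeros there), ",
        "so their draws wander the prior and dominate the convergence flags; ",
        "the likelihood-informed coefficients are unaffected.")
write_fit(fit, file.path(RESULTS_DIR, "fit_subsequent"))

report <- function(draws) {
  list(mean = mean(draws), sd = sd(draws),
       p_greater = format_posterior_p(one_sided_p(draws, "greater")),
       p_smaller = format_posterior_p(one_sided_p(draws, "smaller")))
}
contrasts <- list(
  baseline_ev_partial = report(group_draws(fit, "baselineEV", condition = "partial")),
  baseline_ev_complete = report(group_draws(fit, "baselineEV", condition = "complete")),
  baseline_ev_complete_minus_partial = report(contrast_draws(fit, data.frame(
    coefficient = "baselineEV", condition = c("complete", "partial"),
    weight = c(1, -1)))),
  repetition_partial = report(group_draws(fit, "RB", condition = "partial")),
  repetition_partial_minus_complete = report(contrast_draws(fit, data.frame(
    coefficient = "RB", condition = c("partial", "complete"),
    weight = c(1, -1)))),
  chosen_update_partial = report(group_draws(fit, "dEVchosen", condition = "partial")),
  chosen_update_complete = report(group_draws(fit, "dEVchosen", condition = "complete")),
  counterfactual_update_complete = report(
    group_draws(fit, "dEVunchosen", condition = "complete"))
)
jsonlite::write_json(contrasts,
                     file.path(RESULTS_DIR, "subsequent_choice_contrasts.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("Counterfactual-update coefficient (complete feedback): mean = ",
        round(contrasts$counterfactual_update_complete$mean, 3),
        ", p_greater = ", contrasts$counterfactual_update_complete$p_greater)
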