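#!/usr/bin/env Rscript
# Parameter-recovery validation of the fitting machinery: simulate agents
# with known coefficients (including the strategic-exploration pattern),
# refit, and tabulate truth vs posterior with coverage and bias. Writes
# results/recovery_first.csv and recovery_subsequent.csv.
source("analysis/00_common.R")

message("First-choice model recovery (full study scale) ...")
rec1 <- run_recovery(
  study_agent, model = "first",
  config = task_config(trials_per_session = 100),
  observer = study_observer,
  fit_cfg = script_fit_config(SEED + 3L),
  animals = ANIMALS, sessions_per_condition = SESSIONS_PER_CONDITION,
  feedback = c("partial", "complete"), seed = SEED + 10L)
utils::write.csv(rec1$table, file.path(RESULTS_DIR, "recovery_first.csv"),
                 row.names = FALSE)
g1 <- subset(rec1$table, animal == "group")
message("group-level max |bias| = ", round(max(abs(g1$bias)), 3),
        "; 95% interval coverage = ", round(mean(g1$covered), 2))

message("Subsequent-choice model recovery (complete feedback) ...")
rec2 <- run_recovery(
  study_agent, model = "subsequent",
  config = task_config(trials_per_session = 80),
  observer = study_observer,
  fit_cfg = script_fit_config(SEED + 4L),
  animals = ANIMALS, sessions_per_condition = 6L,
  feedback = "complete", seed = SEED + 11L)
utils::write.csv(rec2$table, file.path(RESULTS_DIR, "recovery_subsequent.csv"),
                 row.names = FALSE)
g2 <- subset(rec2$table, animal == "group")
message("group-level max |bias| = ", round(max(abs(g2$bias)), 3),
        "; 95% interval coverage = ", round(mean(g2$covered), 2))
if (rec1$flagged || rec2$flagged) {
  message("note: reduced-scale MCMC flags ESS < 400 on some parameters; ",
          "raise fit_config() for publication-scale draws")
}
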