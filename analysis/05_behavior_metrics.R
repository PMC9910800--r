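#!/usr/bin/env Rscript
# Descriptive behavioural statistics: model-defined accuracy by condition,
# horizon and choice index (with t tests against chance), the first-choice
# psychometric curve, repetition rates, and within-horizon trend tests.
# Writes results/accuracy.csv, psychometric.csv, repetition.csv and
# metrics_tests.json.
source("analysis/00_common.R")

sessions <- read_sessions(file.path(RESULTS_DIR, "sessions"))

acc <- accuracy_table(sessions, study_observer)
utils::write.csv(acc$by_cell, file.path(RESULTS_DIR, "accuracy.csv"),
                 row.names = FALSE)
message("First-choice accuracy by condition and horizon:")
print(subset(acc$by_cell, choice_index == 1), row.names = FALSE)

# one-sample t tests of per-session first-choice accuracy against 0.5
first <- subset(acc$per_session, choice_index == 1)
acc_tests <- lapply(split(first, first[c("feedback", "horizon")], drop = TRUE),
                    function(g) c(list(n_sessions = nrow(g)),
                                  session_ttest(g$accuracy, 0.5)))
psy <- psychometric_curve(sessions, study_observer, n_bins = 11)
utils::write.csv(psy, file.path(RESULTS_DIR, "psychometric.csv"),
                 row.names = FALSE)

rep_tab <- repetition_table(sessions)
utils::write.csv(rep_tab$by_cell, file.path(RESULTS_DIR, "repetition.csv"),
                 row.names = FALSE)
message("Repetition rate by choice index (long horizon):")
print(rep_tab$by_cell, row.names = FALSE)

trend_acc <- within_horizon_trend(sessions, "accuracy", study_observer)
trend_rep <- within_horizon_trend(sessions, "repetition")
message("Within-horizon accuracy trend: t(", trend_acc$ttest$dof, ") = ",
        round(trend_acc$ttest$t, 2), ", p = ", signif(trend_acc$ttest$p, 3))
message("Within-horizon repetition trend: t(", trend_rep$ttest$dof, ") = ",
        round(trend_rep$ttest$t, 2), ", p = ", signif(trend_rep$ttest$p, 3))

jsonlite::write_json(
  list(accuracy_vs_chance = acc_tests,
       accuracy_trend = trend_acc$ttest, repetition_trend = trend_rep$ttest,
       dropped_sessions = list(accuracy = trend_acc$dropped,
                               repetition = trend_rep$dropped)),
  file.path(RESULTS_DIR, "metrics_tests.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
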