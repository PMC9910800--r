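#!/usr/bin/env Rscript
# Simulate the full study: 3 animals x 13 sessions per feedback condition,
# 100-trial sessions with alternating 5-trial horizon blocks, and a
# strategic-exploration agent making every choice. Writes one CSV per
# session (plus JSON sidecars) under results/sessions/.
source("analysis/00_common.R")

message("Simulating ", length(ANIMALS), " animals x ",
        SESSIONS_PER_CONDITION, " sessions x 2 feedback conditions ...")
sessions <- simulate_experiment(
  study_agent, config = study_task, observer = study_observer,
  animals = ANIMALS, sessions_per_condition = SESSIONS_PER_CONDITION,
  feedback = c("partial", "complete"), seed = SEED)

dir <- file.path(RESULTS_DIR, "sessions")
write_sessions(sessions, dir)

n_choices <- sum(vapply(sessions, function(s) nrow(s$choices), integer(1)))
message("Wrote ", length(sessions), " sessions (", n_choices,
        " choices) to ", dir)
message("Equal-split fraction: ",
        mean(unlist(lapply(sessions, function(s) s$trials$equal_split))))
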