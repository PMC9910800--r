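#!/usr/bin/env Rscript
# Compute the ideal-observer belief trajectories (EV and U per option,
# choice point and information stream) for every simulated session, and a
# small sanity table showing uncertainty falling with the number of
# observations. Writes results/beliefs.csv.
source("analysis/00_common.R")

sessions <- read_sessions(file.path(RESULTS_DIR, "sessions"))
beliefs <- do.call(rbind, lapply(sessions, session_beliefs,
                                 config = study_observer))
utils::write.csv(beliefs, file.path(RESULTS_DIR, "beliefs.csv"),
                 row.names = FALSE)
message("Wrote ", nrow(beliefs), " belief rows")

u_by_n <- aggregate(U ~ n_obs, data = beliefs, FUN = mean)
message("Mean uncertainty by number of observations (should decrease):")
print(u_by_n, row.names = FALSE)
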