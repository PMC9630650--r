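#!/usr/bin/env Rscript
# Simulate one classification session and one force-tracking session
# and write them (plus a summary of the trial plan) under results/.
#
# Desk-scale counts: 2 trials per cell, enough to exercise the full
# session structure; the full study design (50/20 trials per cell)
# is available by raising `trials_per_condition` below.

suppressMessages(library(graspemg))

seed <- 1
out <- "results/sessions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gains <- make_gain_matrix("paperlike")
utils::write.csv(data.frame(channel = rownames(gains), gains),
                 file.path(out, "gain_matrix.csv"), row.names = FALSE)

message("simulating classification session (4 movements x 3 levels) ...")
d1 <- experiment_design(1, trials_per_condition = 2)
s1 <- simulate_session(d1, gains, seed = seed)
write_session(s1, file.path(out, "experiment1"))
message("  ", nrow(s1$annotations), " trials, ",
        round(length(s1$force) / s1$fs / 60, 1), " min of signal")

message("simulating force-tracking sessions (4 movements x 4 profiles) ...")
for (pf in c("rectangular", "triangle", "step_climbing", "random")) {
  d2 <- experiment_design(2, profiles = pf, trials_per_condition = 2)
  s2 <- simulate_session(d2, gains, seed = seed + match(pf, c(
    "rectangular", "triangle", "step_climbing", "random")))
  write_session(s2, file.path(out, paste0("experiment2_", pf)))
  message("  ", pf, ": ", nrow(s2$annotations), " trials")
}
message("sessions written under ", out)
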