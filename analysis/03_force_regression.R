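#!/usr/bin/env Rscript
# Force-estimation study: sliding-window sweep on the staircase
# profile, channel-force correlation table, per-movement channel
# selection, and the movement x profile R^2 table with prediction
# traces. Writes CSVs under results/regression/.

suppressMessages(library(graspemg))

cfg <- run_config(
  experiment = 2, seed = 1,
  trials_per_condition = 8,   # study design uses 20; desk scale here
  sweep_steps = c(40, 80, 160),
  sweep_widths = c(150, 200, 300),
  n_repeats = 5
)

res <- run_experiment_2(cfg, out_dir = "results/regression")

message("\nwindow/step sweep (mean R2 over movements):")
print(subset(res$sweep$table, movement == "mean"), digits = 3)
message("best step: ", res$sweep$best_step_ms, " ms; best width: ",
        res$sweep$best_width_ms, " ms")

message("\nchannel-force correlation (%, mean over trials):")
print(round(res$correlation$mean, 1))

message("\nselected channels per movement (top-4 by correlation):")
for (mv in names(res$channels)) {
  message("  ", mv, ": ", paste(res$channels[[mv]], collapse = ", "))
}

message("\nR2 by movement and profile (%):")
print(res$r2_table, digits = 4)
message("\nresults under results/regression/")
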