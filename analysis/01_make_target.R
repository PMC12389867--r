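#!/usr/bin/env Rscript
# Generate the five-stage bouncing-ball pursuit stimulus and write it as a
# gaze-format CSV, plus a small summary of its geometry (bounce samples,
# per-step speed). The trajectory is fully determined by the seed.

library(spemtrack)

seed <- 7L
dir.create("results", showWarnings = FALSE)

tgt <- generate_target_trajectory(task_config(seed = seed))
save_gaze_csv(tgt, "results/target_seed7.csv")

d <- sqrt(diff(tgt$x)^2 + diff(tgt$y)^2)
bounces <- attr(tgt, "bounces")
summary <- data.frame(
  seed = seed,
  n_samples = n_samples(tgt),
  duration_s = n_samples(tgt) / tgt$rate_hz,
  n_bounces = length(bounces),
  bounce_samples = paste(bounces, collapse = ";"),
  step_px_motion = max(d),
  initial_direction_rad = attr(tgt, "initial_direction")
)
write.csv(summary, "results/target_summary.csv", row.names = FALSE)

message(sprintf("target: %d samples (%.0f s), %d bounce(s) at samples [%s],",
                summary$n_samples, summary$duration_s, summary$n_bounces,
                summary$bounce_samples))
message(sprintf("constant motion step %.4f px (= 250 px/s at 60 Hz); written to results/target_seed7.csv",
                summary$step_px_motion))
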