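#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic cohort.
#
# Two genotypes are simulated at two time points of training: wild-type-like
# mice hold a ~90% success rate on both days, while the disease-model-like
# group starts equally proficient on day 8 but declines to ~30% success and
# longer, more variable reach trajectories by day 45. Every session writes
# its event log, per-trial pose CSVs and the hidden ground truth.

library(mesoreach)

out_root <- "scratch/analysis-run"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(
  out_dir = out_root,
  seed = 20260301L,
  days = c(8L, 45L),
  n_trials = 60L,
  cohort = list(WT = 3L, HD = 3L),
  success_by_day = list(WT = c(0.9, 0.9), HD = c(0.9, 0.3)),
  trajectory_by_day = list(WT = list(mean = c(2.1, 1.9), sd = c(0.62, 0.51)),
                           HD = list(mean = c(2.1, 2.4), sd = c(0.84, 0.95))),
  synth = list(unrewarded_reach_probability = 0.1,
               early_reach_probability = 0.05),
  imaging = list(enabled = TRUE, n_trials = 3L)
)
# keep the imaging stage light: quarter-size frames
cfg$synth$image_shape <- c(64L, 64L)
write_run_config(cfg, file.path(out_root, "run_config.yaml"))

idx <- pipeline_simulate(cfg)
cat(sprintf("simulated %d sessions x %d trials under %s\n",
            nrow(idx), cfg$n_trials, out_root))
print(idx[, c("genotype", "mouse", "day", "seed")])
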