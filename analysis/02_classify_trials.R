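#!/usr/bin/env Rscript
# Stage 2: rule-based behavioral categorization of every trial from pose,
# with a check of recovered categories against the simulator's ground truth.

library(mesoreach)

cfg <- read_run_config("scratch/analysis-run/run_config.yaml")
recs <- pipeline_classify(cfg)

# ground-truth agreement per session (possible only for synthetic cohorts)
idx <- utils::read.csv(file.path(cfg$out_dir, "sessions.csv"))
for (r in seq_len(nrow(idx))) {
  gt <- read_ground_truth(file.path(idx$dir[r], "ground_truth.json"))
  got <- recs[recs$mouse == idx$mouse[r] & recs$day == idx$day[r], ]
  cat(sprintf("%-8s day %2d: %5.1f%% agreement with ground truth\n",
              idx$mouse[r], idx$day[r],
              100 * mean(got$category == gt$true_category)))
}

perf <- summarize_performance(recs)
cat("\nper-day category fractions (pooled over the cohort):\n")
print(perf[, c("day", "success", "partial_fail", "no_reach",
               "unrewarded_reach", "early_reach")])
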