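#!/usr/bin/env Rscript
# Stage 5: genotype x day summary tables and contrasts; copies the small
# final tables into results/tables/ for inspection.

library(mesoreach)

cfg <- read_run_config("scratch/analysis-run/run_config.yaml")
summ <- pipeline_report(cfg)

cat("summary table (one row per genotype x day x mouse):\n")
print(summ[, c("genotype", "mouse", "day", "success", "partial_fail",
               "no_reach", "traj_mean", "traj_sd")], digits = 3)

cat("\ngenotype contrasts (means of per-mouse values, SEM over mice):\n")
for (m in c("success", "traj_mean", "traj_sd")) {
  cat("\n##", m, "\n")
  print(genotype_compare(summ, m, by = "day"), digits = 3)
}

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
for (f in c("summary_table.csv", "contrast_success.csv",
            "contrast_traj_mean.csv", "contrast_traj_sd.csv",
            "roi_peaks.csv", "area_activated.csv")) {
  src <- file.path(cfg$out_dir, f)
  if (file.exists(src)) file.copy(src, file.path("results/tables", f),
                                  overwrite = TRUE)
}
cat("\ncopied final tables to results/tables/\n")
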