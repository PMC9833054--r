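#!/usr/bin/env Rscript
# Stage 3: reach kinematics of successful trials — path length from reward
# delivery to +1.1 s in spout-distance multiples, per-mouse histograms and
# the per-mouse-then-genotype distance statistics.

library(mesoreach)

cfg <- read_run_config("scratch/analysis-run/run_config.yaml")
dists <- pipeline_kinematics(cfg)
dists <- dists[!dists$flagged, ]

for (day in sort(unique(dists$day))) {
  st <- trajectory_stats(dists[dists$day == day, ])
  cat(sprintf("\nday %d genotype distance stats (spout-distance multiples):\n",
              day))
  print(st$per_genotype, digits = 3)
}

cat("\nexample per-mouse histogram (bins are [k, k+1) spout distances):\n")
m1 <- dists[dists$mouse == dists$mouse[1] & dists$day == 8, ]
print(bin_distances(m1$length))
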