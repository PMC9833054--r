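#!/usr/bin/env Rscript
# Stage 4: widefield GCaMP metrics — strobed-channel demultiplexing,
# per-channel percent dF/F, reflectance-based hemodynamic correction,
# atlas-ROI peak amplitudes and activated cortical area for a subset of
# successful trials per session.

library(mesoreach)

cfg <- read_run_config("scratch/analysis-run/run_config.yaml")
peaks <- pipeline_imaging(cfg)

cat("\nrecovered vs configured ROI peak amplitudes (percent dF/F):\n")
agg <- aggregate(cbind(amplitude, true_amplitude) ~ roi, peaks, mean)
print(agg, digits = 3)

areas <- utils::read.csv(file.path(cfg$out_dir, "area_activated.csv"))
cat(sprintf("\nactivated area, first imaged trial per session: %.2f +- %.2f mm^2\n",
            mean(areas$area_mm2), sd(areas$area_mm2)))
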