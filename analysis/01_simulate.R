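#!/usr/bin/env Rscript
# Generate the synthetic inputs used throughout the analysis: the
# study-conditions ellipsoid LV phantom (EDV 150 mL, EF 0.60, 70 bpm, E/A 2,
# 32x32x48 @ 2.5 mm, 30 frames) plus a merged-inflow variant, and write the
# datasets together with their ground-truth curves.

library(lvflow)

dir.create("results/datasets", recursive = TRUE, showWarnings = FALSE)

ph <- make_ellipsoid_lv(noise_sd = 0.01, seed = 1)
write_flow_dataset(ph$dataset, "results/datasets/phantom_default.rds", "rds_bundle")

truth <- data.frame(
  frame = seq_along(ph$dataset$frame_times),
  time_s = ph$dataset$frame_times,
  volume_ml = ph$truth$volume_curve,
  aortic_flow_ml_s = ph$truth$aortic_flow,
  mitral_flow_ml_s = ph$truth$mitral_flow
)
write.csv(truth, "results/phantom_truth_curves.csv", row.names = FALSE)

phm <- make_ellipsoid_lv(e_to_a_ratio = Inf, noise_sd = 0.01, seed = 2)
write_flow_dataset(phm$dataset, "results/datasets/phantom_merged_inflow.rds", "rds_bundle")

cat(sprintf("phantom: EDV %.0f mL, SV %.0f mL, EF %.2f, AVC %.3f s, E/A %.2f\n",
            ph$truth$edv, ph$truth$sv, ph$truth$ef, ph$truth$avc_time,
            ph$truth$e_a_peak_ratio))
cat("wrote results/datasets/*.rds and results/phantom_truth_curves.csv\n")
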