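#!/usr/bin/env Rscript
# Micro-CT morphometry on synthetic otolith phantoms.
#
# Simulates a small cohort of phantoms — young-type specimens with a steep
# otolith boundary and old-type specimens with a blurred one — and runs the
# full quantification chain on each: per-specimen midpoint threshold from
# the paired ROIs, segmentation, volume and mean CT number. Also
# cross-validates CT slice areas against ground-truth cross-sections, the
# in-silico analogue of comparing CT slices to same-thickness histology.

suppressPackageStartupMessages(library(otomorph))
dir.create("results", showWarnings = FALSE)
set.seed(101)

specimens <- expand.grid(age = c("young", "old"), id = 1:4)
specimens$blur_um <- ifelse(specimens$age == "young", 1, 8)

rows <- lapply(seq_len(nrow(specimens)), function(i) {
  ph <- gen_ct_phantom(phantom_params(edge_blur_um = specimens$blur_um[i],
                                      seed = 500 + i))
  thr <- compute_threshold(ph$volume, ph$rois)
  # note: keep_largest stays off here — the phantom's planar striola
  # channel bisects the supra-threshold set, so largest-component
  # filtering would discard one of the two caps
  seg <- segment_otolith(ph$volume, ph$rois$otolith_roi, thr$threshold)
  q <- quantify(ph$volume, seg)
  data.frame(specimen = i, age = specimens$age[i],
             blur_um = specimens$blur_um[i],
             alpha = thr$alpha, beta = thr$beta, threshold = thr$threshold,
             volume_um3 = q$volume_um3, mean_ct = q$mean_ct,
             true_supra_um3 = ph$truth$supra_volume_um3)
})
morpho <- do.call(rbind, rows)
write.csv(morpho, "results/ct_morphometry.csv", row.names = FALSE)

err <- abs(morpho$volume_um3 / morpho$true_supra_um3 - 1) * 100
cat("Per-specimen thresholds span",
    sprintf("%.1f-%.1f CT.", min(morpho$threshold), max(morpho$threshold)),
    "\nYoung (steep boundary): volumes within",
    sprintf("%.2f%%", max(err[morpho$age == "young"])), "of ground truth.",
    "\nOld (blurred boundary): volumes overshoot by up to",
    sprintf("%.1f%%", max(err[morpho$age == "old"])),
    "- the gentle CT slope smears the otolith past its true surface,",
    "\nwhich is the contrast the edge statistic (02) turns into a",
    "measurement.\n")

# slice-area cross-validation on one young specimen
ph <- gen_ct_phantom(phantom_params(edge_blur_um = 1, seed = 500 + 1))
thr <- compute_threshold(ph$volume, ph$rois)
seg <- segment_otolith(ph$volume, ph$rois$otolith_roi, thr$threshold)
ct <- slice_areas(seg, ph$volume$meta)
truth <- slice_areas(ph$truth$supra_mask, ph$volume$meta)
pair <- data.frame(tissue_area_um2 = truth$area_um2,
                   ct_area_um2 = ct$area_um2)
pair <- pair[pair$tissue_area_um2 > 0, ]
reg <- area_regression(pair)
write.csv(cbind(pair, slope = reg$slope, r2 = reg$r2, p = reg$p),
          "results/slice_area_regression.csv", row.names = FALSE)
cat(sprintf(
  "CT areas regress on section areas with slope %.3f, R^2 = %.3f, p = %.2g.\n",
  reg$slope, reg$r2, reg$p))
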