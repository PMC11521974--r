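#!/usr/bin/env Rscript
# The striola edge statistic as a function of boundary blur.
#
# The dual-threshold band (0.9 T <= CT < T) sits on the CT-number slope at
# the striola/extrastriola boundary. A steep (young-type) slope leaves
# almost no voxels in the band; a gentle (old-type) slope fills it. The
# sweep quantifies that mechanism on phantoms whose only difference is the
# Gaussian blur scale of the density field.

suppressPackageStartupMessages(library(otomorph))
dir.create("results", showWarnings = FALSE)

blurs <- c(0, 2, 4, 8, 16)
sweep <- do.call(rbind, lapply(blurs, function(b) {
  ph <- gen_ct_phantom(phantom_params(edge_blur_um = b, seed = 42))
  thr <- compute_threshold(ph$volume, ph$rois)
  ev <- striola_edge_volume(ph$volume, ph$rois$otolith_roi, thr)
  data.frame(blur_um = b, threshold = thr$threshold,
             edge_lower = thr$edge_lower,
             edge_voxels = ev$edge_voxels,
             edge_volume_um3 = ev$edge_volume_um3)
}))
write.csv(sweep, "results/edge_blur_sweep.csv", row.names = FALSE)

rho <- cor(sweep$blur_um, sweep$edge_volume_um3, method = "spearman")
cat("Edge volume grows from",
    sprintf("%.3g to %.3g um^3", min(sweep$edge_volume_um3),
            max(sweep$edge_volume_um3)),
    "across blur 0-16 um; Spearman rho =", rho, "\n")
stopifnot(all(diff(sweep$edge_volume_um3) > 0))
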