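# Independent oracles used across the suite.

# Exhaustive voxel-scan segmentation: explicit triple loop, no vectorized
# shortcuts, deliberately independent of segment_otolith().
oracle_segment <- function(voxels, roi, threshold) {
  d <- dim(voxels)
  out <- array(FALSE, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1]))
        if (roi[i, j, k] && voxels[i, j, k] >= threshold)
          out[i, j, k] <- TRUE
  out
}

# Exhaustive dual-threshold edge scan: edge_lower <= CT < threshold.
oracle_edge <- function(voxels, roi, threshold, edge_lower) {
  d <- dim(voxels)
  out <- array(FALSE, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      for (i in seq_len(d[1]))
        if (roi[i, j, k] && voxels[i, j, k] >= edge_lower &&
            voxels[i, j, k] < threshold)
          out[i, j, k] <- TRUE
  out
}

# Random test volume + ROI on a small grid.
random_volume_case <- function(seed, max_dim = 32L) {
  set.seed(seed)
  d <- sample(4:max_dim, 3, replace = TRUE)
  voxels <- array(rnorm(prod(d), 100, 40), d)
  roi <- array(runif(prod(d)) < 0.6, d)
  if (!any(roi)) roi[1] <- TRUE
  list(voxels = voxels, roi = roi, threshold = rnorm(1, 100, 20))
}

# Classical balanced two-way ANOVA by explicit sum-of-squares decomposition.
oracle_two_way_F <- function(value, A, B) {
  gm <- mean(value)
  ssA <- sum(tapply(value, A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(value, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(value, list(A, B), mean)
  nc <- table(A, B)[1, 1]
  am <- tapply(value, A, mean)
  bm <- tapply(value, B, mean)
  ssAB <- nc * sum((sweep(sweep(cellm, 1, am), 2, bm) + gm)^2)
  sse <- sum((value - cellm[cbind(A, B)])^2)
  dfe <- length(value) - length(am) * length(bm)
  list(F_A = (ssA / (length(am) - 1)) / (sse / dfe),
       F_B = (ssB / (length(bm) - 1)) / (sse / dfe),
       F_AB = (ssAB / ((length(am) - 1) * (length(bm) - 1))) / (sse / dfe),
       df_resid = dfe)
}

# Small phantom parameters used where full default size is not needed.
small_phantom <- function(..., seed = 1) {
  phantom_params(grid = c(40L, 40L, 40L), spacing_um = c(5, 5, 5),
                 semi_axes_um = c(30, 45, 60), seed = seed, ...)
}

# 2D rotation applied to both point sets of a layer trace.
rotate_trace <- function(trace, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  list(les_points = trace$les_points %*% t(R),
       base_points = trace$base_points %*% t(R))
}
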