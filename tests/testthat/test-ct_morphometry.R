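# A tiny two-compartment volume with constant ROI values, used for the
# exact threshold-arithmetic cases.
constant_roi_volume <- function(hi, lo) {
  arr <- array(lo, c(6, 6, 6))
  roi_o <- array(FALSE, c(6, 6, 6)); roi_o[2:3, 2:3, 2:3] <- TRUE
  roi_t <- array(FALSE, c(6, 6, 6)); roi_t[5:6, 5:6, 5:6] <- TRUE
  arr[roi_o] <- hi
  list(vol = ct_volume(arr, volume_meta(c(10, 10, 10))),
       rois = roi_pair(roi_o, roi_t))
}

test_that("roi_histogram conserves counts and localizes the two modes", {
  cs <- constant_roi_volume(5, 5)
  h <- roi_histogram(cs$vol, cs$rois$otolith_roi, n_bins = 16)
  expect_equal(sum(h$counts), sum(cs$rois$otolith_roi))
  expect_equal(sum(h$counts > 0), 1L)  # constant ROI: one occupied bin

  ph <- gen_ct_phantom(small_phantom(seed = 2))
  ho <- roi_histogram(ph$volume, ph$rois$otolith_roi, 128)
  ht <- roi_histogram(ph$volume, ph$rois$tissue_roi, 128)
  expect_equal(sum(ho$counts), sum(ph$rois$otolith_roi))
  expect_lt(abs(ht$mids[which.max(ht$counts)] - 50), 10)
  # otolith ROI is bimodal (it includes surrounding fluid); the high mode
  # sits at mu_otolith
  hi <- ho$mids > 125
  expect_lt(abs(ho$mids[hi][which.max(ho$counts[hi])] - 200), 10)
  expect_error(roi_histogram(ph$volume, array(FALSE, dim(ph$volume$voxels))),
               "empty")
})

test_that("midpoint threshold and 0.9 edge bound are exact", {
  cs <- constant_roi_volume(100, 20)
  thr <- compute_threshold(cs$vol, cs$rois)
  expect_equal(thr$alpha, 100)
  expect_equal(thr$beta, 20)
  expect_equal(thr$threshold, 60)
  expect_equal(thr$edge_lower, 54)

  cs2 <- constant_roi_volume(200, 50)
  thr2 <- compute_threshold(cs2$vol, cs2$rois)
  expect_equal(thr2$threshold, 125)
  expect_equal(thr2$edge_lower, 112.5)

  expect_error(compute_threshold(constant_roi_volume(50, 50)$vol,
                                 cs$rois), "contrast")
  # mode summary agrees on constant regions to half-bin resolution
  thr3 <- compute_threshold(cs2$vol, cs2$rois, summary = "mode")
  expect_equal(thr3$threshold, 125, tolerance = 1e-4)
})

test_that("segmentation matches the exhaustive voxel-scan oracle", {
  for (s in 1:20) {
    cs <- random_volume_case(s, max_dim = 16L)
    seg <- segment_otolith(ct_volume(cs$voxels), cs$roi, cs$threshold)
    expect_identical(seg, oracle_segment(cs$voxels, cs$roi, cs$threshold))
  }
})

test_that("segmentation respects threshold extremes and monotonicity", {
  cs <- random_volume_case(99, max_dim = 12L)
  vol <- ct_volume(cs$voxels)
  expect_equal(segment_otolith(vol, cs$roi, min(cs$voxels) - 1), cs$roi)
  expect_warning(empty <- segment_otolith(vol, cs$roi, max(cs$voxels) + 1),
                 "empty")
  expect_false(any(empty))
  # T1 <= T2 implies seg(T2) subset of seg(T1)
  for (s in 1:10) {
    cs <- random_volume_case(100 + s, max_dim = 12L)
    vol <- ct_volume(cs$voxels)
    t1 <- quantile(cs$voxels, 0.3)
    t2 <- quantile(cs$voxels, 0.7)
    s1 <- segment_otolith(vol, cs$roi, t1)
    s2 <- segment_otolith(vol, cs$roi, t2)
    expect_true(all(s1[s2]))
    expect_lte(sum(s2), sum(s1))
  }
})

test_that("26-connected component labelling behaves at corners", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # touch only diagonally
  lab <- otomorph:::label_components_26(m)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])  # one 26-component
  m[3, 1, 3] <- TRUE                        # isolated from (1,1,1)? shares corner with (2,2,2)
  lab <- otomorph:::label_components_26(m)
  expect_equal(length(unique(lab[m])), 1L)
  m2 <- array(FALSE, c(5, 5, 5))
  m2[1, 1, 1] <- TRUE; m2[5, 5, 5] <- TRUE
  expect_equal(length(unique(otomorph:::label_components_26(m2)[m2])), 2L)
})

test_that("keep_largest retains the dominant component only", {
  arr <- array(0, c(8, 8, 8))
  arr[2:4, 2:4, 2:4] <- 100   # 27-voxel blob
  arr[7, 7, 7] <- 100         # stray voxel
  vol <- ct_volume(arr)
  roi <- array(TRUE, c(8, 8, 8))
  seg <- segment_otolith(vol, roi, 50, keep_largest = TRUE)
  expect_equal(sum(seg), 27)
  expect_false(seg[7, 7, 7])
})

test_that("quantify converts counts to volume and averages raw CT", {
  arr <- array(0, c(5, 5, 5)); arr[1:10] <- 7
  vol <- ct_volume(arr, volume_meta(c(10, 10, 10)))
  seg <- array(FALSE, c(5, 5, 5)); seg[1:10] <- TRUE
  q <- quantify(vol, seg)
  expect_equal(q$volume_um3, 10000)
  expect_equal(q$mean_ct, 7)
  q0 <- quantify(vol, array(FALSE, c(5, 5, 5)))
  expect_equal(q0$volume_um3, 0)
  expect_true(is.na(q0$mean_ct))
})

test_that("noiseless phantom is recovered exactly by the full chain", {
  ph <- gen_ct_phantom(small_phantom(noise_sd = 0))
  thr <- compute_threshold(ph$volume, ph$rois)
  seg <- segment_otolith(ph$volume, ph$rois$otolith_roi, thr$threshold)
  q <- quantify(ph$volume, seg)
  expect_equal(q$mean_ct, ph$params$mu_otolith)       # exactly mu_otolith
  expect_equal(sum(seg), sum(ph$truth$supra_mask))    # striola excluded
  expect_gte(q$mean_ct, thr$threshold)                # mean over supra voxels
})

test_that("edge set equals the brute-force band and is disjoint from the core", {
  for (s in 1:10) {
    cs <- random_volume_case(200 + s, max_dim = 14L)
    vol <- ct_volume(cs$voxels)
    thr <- structure(list(alpha = 150, beta = 50, threshold = 100,
                          edge_lower = 90, summary = "mean"),
                     class = "threshold_result")
    ev <- striola_edge_volume(vol, cs$roi, thr)
    expect_identical(ev$edge_mask, oracle_edge(cs$voxels, cs$roi, 100, 90))
    core <- segment_otolith(vol, cs$roi, 100)
    expect_false(any(ev$edge_mask & core))
    lo <- segment_otolith(vol, cs$roi, 90)
    expect_identical(ev$edge_mask | core, lo)
  }
})

test_that("slice areas obey the volume identity and analytic cross-sections", {
  ph <- gen_ct_phantom(small_phantom(noise_sd = 0))
  seg <- ph$truth$otolith_mask
  sa <- slice_areas(seg, ph$volume$meta, axis = "z")
  expect_equal(nrow(sa), dim(seg)[1])
  expect_equal(sum(sa$area_um2) * ph$volume$meta$spacing_um[1],
               sum(seg) * prod(ph$volume$meta$spacing_um))
  expect_equal(sa$area_um2[1], 0)  # empty top slice
  # sphere: central-slice areas near analytic pi * (R^2 - z^2)
  sp <- phantom_params(grid = c(80L, 80L, 80L), spacing_um = c(2, 2, 2),
                       semi_axes_um = c(60, 60, 60), noise_sd = 0,
                       striola_width_um = 0, roi_dilate_um = 4)
  phs <- gen_ct_phantom(sp)
  sas <- slice_areas(phs$truth$otolith_mask, phs$volume$meta, axis = "z")
  ctr <- (80 - 1) / 2 * 2
  z <- (sas$slice - 1) * 2 - ctr
  analytic <- pi * pmax(60^2 - z^2, 0)
  mid <- abs(z) < 45   # away from the poles, where voxelization dominates
  expect_lt(max(abs(sas$area_um2[mid] / analytic[mid] - 1)), 0.05)
})
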