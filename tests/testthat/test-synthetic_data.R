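test_that("noise- and blur-free phantom takes exactly three density values", {
  ph <- gen_ct_phantom(small_phantom(noise_sd = 0, edge_blur_um = 0))
  vals <- sort(unique(as.numeric(ph$volume$voxels)))
  p <- ph$params
  striola_val <- p$mu_otolith - p$striola_depth * (p$mu_otolith - p$mu_background)
  expect_equal(vals, sort(c(p$mu_background, striola_val, p$mu_otolith)))
  # values land on the right masks
  expect_true(all(ph$volume$voxels[ph$truth$striola_mask] == striola_val))
  expect_true(all(ph$volume$voxels[ph$truth$supra_mask] == p$mu_otolith))
})

test_that("striola_depth = 0 gives a plain ellipsoid with empty striola", {
  ph <- gen_ct_phantom(small_phantom(noise_sd = 0, striola_depth = 0))
  expect_equal(sum(ph$truth$striola_mask), 0)
  expect_equal(length(unique(as.numeric(ph$volume$voxels))), 2L)
})

test_that("voxelized ellipsoid volume converges to the analytic volume", {
  # spec'd case: semi-axes (100, 60, 40) um at 5 um spacing, within 2%
  p5 <- phantom_params(grid = c(96L, 96L, 96L), spacing_um = c(5, 5, 5),
                       semi_axes_um = c(100, 60, 40), noise_sd = 0)
  ph5 <- gen_ct_phantom(p5)
  err5 <- abs(ph5$truth$volume_um3 / ph5$truth$analytic_volume_um3 - 1)
  expect_lt(err5, 0.02)
  # halving the spacing at least halves the error
  p25 <- phantom_params(grid = c(192L, 192L, 192L),
                        spacing_um = c(2.5, 2.5, 2.5),
                        semi_axes_um = c(100, 60, 40), noise_sd = 0)
  ph25 <- gen_ct_phantom(p25)
  err25 <- abs(ph25$truth$volume_um3 / ph25$truth$analytic_volume_um3 - 1)
  expect_lt(err25, err5 / 2)
})

test_that("phantom rejects an ellipsoid that does not fit the grid", {
  expect_error(phantom_params(grid = c(20L, 20L, 20L),
                              semi_axes_um = c(60, 60, 60), seed = 1),
               "exceeds the grid")
})

test_that("phantom ROIs are valid and ground truth sits inside the otolith ROI", {
  ph <- gen_ct_phantom(small_phantom(seed = 3))
  expect_s3_class(ph$rois, "roi_pair")
  expect_true(all(ph$rois$otolith_roi[ph$truth$otolith_mask]))
  expect_false(any(ph$rois$otolith_roi & ph$rois$tissue_roi))
})

test_that("sled trapezoid attains its bounds and per-leg travel exactly", {
  p <- sled_params()
  tr <- gen_sled_trace(p)
  expect_equal(max(abs(tr$acceleration_mm_s2)) / 1000, p$a_max)
  expect_equal(max(abs(tr$velocity_mm_s)) / 1000, p$v_max)
  expect_equal(range(tr$position_mm), c(0, 1800))
  # dwells are exactly 0.3 s * 240 Hz = 72 zero-velocity samples
  r <- rle(tr$velocity_mm_s == 0)
  expect_true(all(r$lengths[r$values] == 72L))
  expect_equal(sum(r$values), 11L)  # initial + after each of 10 legs
})

test_that("sled velocity integrates the position and legs travel 1800 mm", {
  tr <- gen_sled_trace(sled_params(n_round_trips = 2L))
  dt <- 1 / attr(tr, "rate_hz")
  # trapezoidal integration of the analytic velocity reproduces position
  pos_int <- tr$position_mm[1] +
    c(0, cumsum((tr$velocity_mm_s[-1] + tr$velocity_mm_s[-nrow(tr)]) / 2 * dt))
  # within one sample's travel at v_max
  expect_lt(max(abs(pos_int - tr$position_mm)), 3250 * dt)
})

test_that("infeasible sled kinematics are rejected by name", {
  expect_error(sled_params(a_max = 1, v_max = 3, distance_m = 1.8),
               "infeasible")
})

test_that("noise-free eye trace is an exact affine function of acceleration", {
  tr <- gen_sled_trace(sled_params(n_round_trips = 1L))
  eye <- gen_eye_trace(tr, eye_model_params(gain_deg_per_G = 2,
                                            noise_sd_deg = 0,
                                            drift_deg_per_s = 0.1))
  expected <- 2 * tr$acceleration_mm_s2 / 1000 / 9.81 + 0.1 * tr$t
  expect_equal(eye$eye_y_deg, expected, tolerance = 1e-12)
  expect_equal(max(eye$eye_y_deg - 0.1 * eye$t), 2 * 1.3, tolerance = 1e-9)
})

test_that("zero-gain eye trace is pure noise at the requested level", {
  tr <- gen_sled_trace(sled_params())
  eye <- gen_eye_trace(tr, eye_model_params(gain_deg_per_G = 0,
                                            noise_sd_deg = 0.5, seed = 9))
  expect_equal(sd(eye$eye_y_deg), 0.5, tolerance = 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_ct_phantom(small_phantom(seed = 7))
  b <- gen_ct_phantom(small_phantom(seed = 7))
  expect_identical(a$volume$voxels, b$volume$voxels)
  tr <- gen_sled_trace(sled_params(n_round_trips = 1L))
  e1 <- gen_eye_trace(tr, eye_model_params(seed = 7))
  e2 <- gen_eye_trace(tr, eye_model_params(seed = 7))
  expect_identical(e1$eye_y_deg, e2$eye_y_deg)
  c1 <- gen_cohort(cohort_effects(seed = 7))
  c2 <- gen_cohort(cohort_effects(seed = 7))
  expect_identical(c1$value, c2$value)
  l1 <- gen_layer_points(30, 20, 1, seed = 7)
  l2 <- gen_layer_points(30, 20, 1, seed = 7)
  expect_identical(l1$les_points, l2$les_points)
})

test_that("randomized generators insist on an explicit seed", {
  expect_error(small_phantom(seed = NULL), "seed")
  expect_error(gen_layer_points(30, 20, noise_um = 1), "seed")
  expect_error(cohort_effects(), "seed")
  expect_error(eye_model_params(noise_sd_deg = 0.1), "seed")
})

test_that("layer tracings at the extremes give exact angles", {
  expect_equal(layer_angle(gen_layer_points(90, 10, 0))$angle_deg, 90)
  expect_equal(layer_angle(gen_layer_points(0, 10, 0))$angle_deg, 0)
  expect_error(gen_layer_points(45, n_points = 1), ">= 2")
})

test_that("cohort table has the 2x2 per-ear structure and additive effects", {
  m <- default_cohort_measures()
  m$residual_sd[] <- 1e-9
  co <- gen_cohort(cohort_effects(n_per_cell = 4, measures = m, seed = 1))
  expect_equal(nrow(co), 4 * 4 * nrow(m))
  d <- co[co$measurement == "density_ct", ]
  cells <- tapply(d$value, list(d$age_group, d$sex), mean)
  expect_equal(cells["young", "female"], 600, tolerance = 1e-6)
  expect_equal(cells["old", "female"], 540, tolerance = 1e-6)
  expect_equal(cells["young", "male"], 610, tolerance = 1e-6)
})
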