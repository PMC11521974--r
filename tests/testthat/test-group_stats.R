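test_that("normality screen passes Gaussian samples and rejects two-point mass", {
  pass <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(rnorm(200), warn = FALSE)$pass
  }, logical(1))
  expect_gte(mean(pass), 0.90)

  set.seed(1)
  x <- sample(c(0, 10), 200, replace = TRUE)
  expect_false(normality_screen(x, warn = FALSE)$pass)
  expect_error(normality_screen(c(1, 2)), "n >= 3")
})

test_that("two-way ANOVA matches the brute-force sum-of-squares oracle on balanced data", {
  for (s in 1:5) {
    set.seed(s)
    d <- expand.grid(age_group = c("young", "old"),
                     sex = c("female", "male"), rep = 1:4)
    d$measurement <- "m"
    d$value <- rnorm(16) + 1.5 * (d$age_group == "old") +
      0.8 * (d$sex == "male") * (d$age_group == "old")
    av <- two_way_anova(d, "m")
    orc <- oracle_two_way_F(d$value, d$age_group, d$sex)
    expect_equal(av$effects$F[av$effects$effect == "age"], orc$F_A,
                 tolerance = 1e-9)
    expect_equal(av$effects$F[av$effects$effect == "sex"], orc$F_B,
                 tolerance = 1e-9)
    expect_equal(av$effects$F[av$effects$effect == "interaction"],
                 orc$F_AB, tolerance = 1e-9)
    expect_equal(av$df_resid, orc$df_resid)
    expect_true(all(av$effects$p >= 0 & av$effects$p <= 1))
  }
})

test_that("ANOVA handles unbalanced cells and rejects missing levels", {
  co <- gen_cohort(cohort_effects(n_per_cell = 10, seed = 3))
  co <- co[-1, ]  # drop one ear: n = 39, unbalanced
  av <- two_way_anova(co, "density_ct")
  expect_equal(av$n, 39)
  expect_true(all(is.finite(av$effects$F)))
  young_only <- co[co$age_group == "young", ]
  expect_error(two_way_anova(young_only, "density_ct"), "both levels")
})

test_that("age effect of twice the residual sd is detected with high power", {
  m <- default_cohort_measures()[1, ]
  m$age_effect <- 2 * m$residual_sd
  m$sex_effect <- 0
  m$interaction_effect <- 0
  hits <- vapply(1:50, function(s) {
    co <- gen_cohort(cohort_effects(n_per_cell = 10, measures = m,
                                    seed = 5000 + s))
    av <- two_way_anova(co, "density_ct")
    av$effects$p[av$effects$effect == "age"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("Bonferroni adjustment multiplies, caps, and flags primary contrasts", {
  co <- gen_cohort(cohort_effects(n_per_cell = 6, seed = 9))
  ph <- bonferroni_posthoc(co, "density_ct")
  expect_equal(nrow(ph), 6L)
  expect_equal(attr(ph, "m"), 6L)
  expect_equal(ph$p_adj, pmin(1, 6 * ph$p_raw))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_equal(sum(ph$primary_contrast), 4L)

  ph4 <- bonferroni_posthoc(co, "density_ct", family = "primary")
  expect_equal(nrow(ph4), 4L)
  expect_equal(ph4$p_adj, pmin(1, 4 * ph4$p_raw))

  # identical cell distributions: every adjusted p hits the cap region
  m0 <- default_cohort_measures()[1, ]
  m0$age_effect <- 0; m0$sex_effect <- 0; m0$interaction_effect <- 0
  capped <- vapply(1:20, function(s) {
    co0 <- gen_cohort(cohort_effects(n_per_cell = 8, measures = m0,
                                     seed = 800 + s))
    mean(bonferroni_posthoc(co0, "density_ct")$p_adj == 1)
  }, numeric(1))
  expect_gt(mean(capped), 0.5)  # most null comparisons cap at 1
})

test_that("a single shifted cell drives only its own comparisons", {
  hits <- vapply(1:20, function(s) {
    m <- default_cohort_measures()[1, ]
    m$age_effect <- 0; m$sex_effect <- 0
    m$interaction_effect <- 5 * m$residual_sd  # shifts old_male only
    co <- gen_cohort(cohort_effects(n_per_cell = 10, measures = m,
                                    seed = 300 + s))
    ph <- bonferroni_posthoc(co, "density_ct")
    with_om <- ph$group1 == "old_male" | ph$group2 == "old_male"
    all(ph$p_adj[with_om] < 0.05) && all(ph$p_adj[!with_om] > 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("area regression recovers exact and constructed relations", {
  d <- data.frame(tissue_area_um2 = 1:10, ct_area_um2 = 2 * (1:10))
  r <- suppressWarnings(area_regression(d))  # exact fit: summary.lm warns
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_error(area_regression(
    data.frame(tissue_area_um2 = rep(1, 5), ct_area_um2 = 1:5)),
    "constant")

  # CT slice areas against ground-truth cross sections from one phantom
  ph <- gen_ct_phantom(small_phantom(seed = 12))
  thr <- compute_threshold(ph$volume, ph$rois)
  seg <- segment_otolith(ph$volume, ph$rois$otolith_roi, thr$threshold)
  ct <- slice_areas(seg, ph$volume$meta)
  truth <- slice_areas(ph$truth$supra_mask, ph$volume$meta)
  keep <- truth$area_um2 > 0
  r2 <- area_regression(data.frame(tissue_area_um2 = truth$area_um2[keep],
                                   ct_area_um2 = ct$area_um2[keep]))
  expect_gt(r2$slope, 0)
  expect_lt(r2$p, 0.001)
  expect_gt(r2$r2, 0.9)

  # independent noise: slope test is non-significant most of the time
  nulls <- vapply(1:40, function(s) {
    set.seed(s)
    area_regression(data.frame(tissue_area_um2 = rnorm(50),
                               ct_area_um2 = rnorm(50)))$p > 0.05
  }, logical(1))
  expect_gte(mean(nulls), 0.85)
})
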