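# Synthetic age-by-sex cohorts.
#
# Each ear contributes one record per measurement, generated from a 2x2
# cell-means model with additive age, sex and interaction shifts and
# homoscedastic Gaussian residuals — the structure the downstream two-way
# ANOVA assumes. Default effect directions follow the aging phenotype the
# pipeline is built to detect: lower otolith density, larger striola edge
# volume, smaller layer angle, and a smaller otolith function index in old
# animals.

#' Default cohort measurement structure
#'
#' One row per measurement the pipeline produces, with baseline, additive
#' old-age / male / interaction shifts, and residual s.d. Edit a copy of
#' this table to change the simulated effect structure.
#'
#' @return data.frame, see [cohort_effects()].
#' @export
default_cohort_measures <- function() {
  data.frame(
    measurement = c("density_ct", "edge_volume_um3", "layer_angle_deg",
                    "lvor_index_deg"),
    baseline    = c(600,   1e5,  55,  2.0),
    age_effect  = c(-60,   4e4, -15, -0.6),
    sex_effect  = c(10,    0,     0, -0.3),
    interaction_effect = c(0, 0, 0, 0),
    residual_sd = c(60,    3e4,  10,  0.5))
}

#' Cohort effect-structure parameters
#'
#' @param n_per_cell ears per (age, sex) cell (>= 2). Default 10, giving
#'   n = 40 as in a 2x2 cohort of twenty animals measured on both ears.
#' @param measures data.frame with columns `measurement`, `baseline`,
#'   `age_effect`, `sex_effect`, `interaction_effect`, `residual_sd`.
#'   Effects are additive shifts applied for old age, male sex, and their
#'   combination; `residual_sd` must be > 0.
#' @param seed integer seed, required.
#' @return a validated list of class `cohort_effects`.
#' @export
cohort_effects <- function(n_per_cell = 10L,
                           measures = default_cohort_measures(),
                           seed = NULL) {
  if (!is.numeric(n_per_cell) || n_per_cell < 2)
    stop_input("`n_per_cell` must be >= 2")
  need <- c("measurement", "baseline", "age_effect", "sex_effect",
            "interaction_effect", "residual_sd")
  if (!is.data.frame(measures) || !all(need %in% names(measures)))
    stop_input("`measures` must have columns: ", paste(need, collapse = ", "))
  if (any(measures$residual_sd <= 0))
    stop_input("`residual_sd` must be > 0 for every measurement")
  structure(list(n_per_cell = as.integer(n_per_cell), measures = measures,
                 seed = assert_seed(seed)),
            class = "cohort_effects")
}

#' Generate a synthetic per-ear cohort table
#'
#' @param e a [cohort_effects()] object.
#' @return data.frame with columns `mouse_id`, `ear` (`"left"`/`"right"`),
#'   `age_group` (`"young"`/`"old"`), `sex` (`"female"`/`"male"`),
#'   `measurement`, `value`. Ears are treated as independent observations,
#'   mirroring the per-ear analysis the statistics module performs.
#' @export
gen_cohort <- function(e) {
  if (!inherits(e, "cohort_effects")) stop_input("`e` must be cohort_effects")
  set.seed(e$seed)
  cells <- expand.grid(age_group = c("young", "old"),
                       sex = c("female", "male"),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    age <- cells$age_group[ci]
    sex <- cells$sex[ci]
    ear <- rep(c("left", "right"), length.out = e$n_per_cell)
    mouse <- sprintf("%s_%s_m%02d", substr(age, 1, 1), substr(sex, 1, 1),
                     ceiling(seq_len(e$n_per_cell) / 2))
    for (mi in seq_len(nrow(e$measures))) {
      m <- e$measures[mi, ]
      mu <- m$baseline + m$age_effect * (age == "old") +
        m$sex_effect * (sex == "male") +
        m$interaction_effect * (age == "old" && sex == "male")
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = mouse, ear = ear, age_group = age, sex = sex,
        measurement = m$measurement,
        value = mu + stats::rnorm(e$n_per_cell, sd = m$residual_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
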