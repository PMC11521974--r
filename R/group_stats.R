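# Cohort statistics: the study's analysis pathway.
#
# Every measurement is screened for normality (Shapiro-Wilk plus a
# Kolmogorov-Smirnov test against a normal with the sample's moments),
# then analyzed by two-way age x sex ANOVA with interaction using Type III
# sums of squares and sum-to-zero contrasts (the SPSS convention, robust
# to mildly unbalanced cells such as a cohort that lost one animal). When
# the interaction is significant, Bonferroni-corrected pairwise t tests
# among the four age-by-sex cells localize the effect. Significance is
# fixed at p < 0.05 throughout.

#' Normality screen for one sample
#'
#' Shapiro-Wilk and Kolmogorov-Smirnov tests; the KS test compares against
#' a normal with the sample's own mean and s.d. (Lilliefors-style, so its
#' p value is conservative). The screen passes when both p values are at
#' or above 0.05; a failing screen warns but does not stop the pipeline.
#'
#' @param values numeric sample, n >= 3.
#' @param warn emit a warning on failure (default `TRUE`).
#' @return list with `shapiro_p`, `ks_p`, `pass`.
#' @export
normality_screen <- function(values, warn = TRUE) {
  values <- values[is.finite(values)]
  if (length(values) < 3L)
    stop_input("normality screen needs n >= 3")
  sh <- stats::shapiro.test(values)$p.value
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value)
  pass <- sh >= 0.05 && ks >= 0.05
  if (!pass && warn)
    warning(sprintf(
      "normality screen failed (Shapiro p = %.3g, KS p = %.3g); proceeding with ANOVA",
      sh, ks), call. = FALSE)
  list(shapiro_p = sh, ks_p = ks, pass = pass)
}

check_cohort <- function(table, measurement) {
  need <- c("age_group", "sex", "measurement", "value")
  if (!all(need %in% names(table)))
    stop_input("cohort table needs columns: ", paste(need, collapse = ", "))
  d <- table[table$measurement == measurement, ]
  if (nrow(d) == 0L)
    stop_input(sprintf("no records for measurement \"%s\"", measurement))
  if (length(unique(d$age_group)) < 2L || length(unique(d$sex)) < 2L)
    stop_input("both levels of age_group and sex must be present")
  d$age_group <- factor(d$age_group, levels = c("young", "old"))
  d$sex <- factor(d$sex, levels = c("female", "male"))
  if (any(is.na(d$age_group)) || any(is.na(d$sex)))
    stop_input("age_group must be young/old and sex female/male")
  d
}

#' Two-way age x sex ANOVA with interaction
#'
#' @param table cohort data.frame (columns `age_group`, `sex`,
#'   `measurement`, `value`); ears are independent observations.
#' @param measurement which measurement to analyze.
#' @param type sums-of-squares type: `3` (default, sum-to-zero contrasts)
#'   or `2`.
#' @param rank_transform analyze ranks instead of raw values (fallback for
#'   non-normal data). Default `FALSE`.
#' @return list of class `anova_result`: `effects` data.frame (rows age,
#'   sex, interaction with `F`, `p`, `df`), `n`, `df_resid`, `measurement`.
#' @export
two_way_anova <- function(table, measurement, type = 3,
                          rank_transform = FALSE) {
  d <- check_cohort(table, measurement)
  if (min(table(d$age_group, d$sex)) < 2L)
    stop_input("each age x sex cell needs >= 2 records")
  if (rank_transform) d$value <- rank(d$value)
  fit <- stats::lm(value ~ age_group * sex, data = d,
                   contrasts = list(age_group = "contr.sum",
                                    sex = "contr.sum"))
  a <- car::Anova(fit, type = type)
  pick <- function(term) {
    i <- match(term, rownames(a))
    c(F = a[i, "F value"], df = a[i, "Df"], p = a[i, "Pr(>F)"])
  }
  eff <- rbind(age = pick("age_group"), sex = pick("sex"),
               interaction = pick("age_group:sex"))
  effects <- data.frame(effect = rownames(eff), F = eff[, "F"],
                        df = eff[, "df"], p = eff[, "p"],
                        row.names = NULL)
  structure(list(effects = effects, n = nrow(d),
                 df_resid = fit$df.residual, measurement = measurement),
            class = "anova_result")
}

#' Bonferroni-corrected post-hoc comparisons among the four cells
#'
#' Pairwise pooled-variance t tests among the young-female, young-male,
#' old-female and old-male cells, with adjusted p = min(1, m * p_raw).
#' With `family = "all_pairs"` all six pairs are tested (m = 6); with
#' `family = "primary"` only the four interpretable contrasts — sex within
#' each age and age within each sex (m = 4). The four primary contrasts
#' are flagged in the output either way.
#'
#' @param table cohort data.frame.
#' @param measurement which measurement to analyze.
#' @param family `"all_pairs"` (default) or `"primary"`.
#' @return data.frame of class `posthoc_result`: `group1`, `group2`,
#'   `t`, `df`, `p_raw`, `p_adj`, `primary_contrast`, attribute `m`.
#' @export
bonferroni_posthoc <- function(table, measurement,
                               family = c("all_pairs", "primary")) {
  family <- match.arg(family)
  d <- check_cohort(table, measurement)
  d$cell <- paste(d$age_group, d$sex, sep = "_")
  cells <- c("young_female", "young_male", "old_female", "old_male")
  if (any(table(factor(d$cell, levels = cells)) == 0L))
    stop_input("all four age x sex cells must be non-empty")
  pairs <- utils::combn(cells, 2)
  is_primary <- function(g1, g2) {
    a1 <- sub("_.*", "", g1); s1 <- sub(".*_", "", g1)
    a2 <- sub("_.*", "", g2); s2 <- sub(".*_", "", g2)
    (a1 == a2) != (s1 == s2)  # exactly one factor differs
  }
  prim <- apply(pairs, 2, function(p) is_primary(p[1], p[2]))
  if (family == "primary") pairs <- pairs[, prim, drop = FALSE]
  m <- ncol(pairs)
  res <- apply(pairs, 2, function(p) {
    tt <- stats::t.test(d$value[d$cell == p[1]], d$value[d$cell == p[2]],
                        var.equal = TRUE)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = res["t", ], df = res["df", ],
                    p_raw = res["p_raw", ],
                    p_adj = pmin(1, m * res["p_raw", ]),
                    primary_contrast = apply(pairs, 2, function(p)
                      is_primary(p[1], p[2])))
  attr(out, "m") <- m
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Regression of CT slice areas on histology slice areas
#'
#' Ordinary least squares with the tissue-section area as the explanatory
#' variable and the CT area as the response, validating that CT slices
#' measure the same cross-sections as same-thickness histology.
#'
#' @param areas data.frame with columns `tissue_area_um2` and
#'   `ct_area_um2`, >= 3 paired rows.
#' @return list with `slope`, `intercept`, `r2`, `p` (slope test).
#' @export
area_regression <- function(areas) {
  need <- c("tissue_area_um2", "ct_area_um2")
  if (!is.data.frame(areas) || !all(need %in% names(areas)))
    stop_input("`areas` needs columns tissue_area_um2 and ct_area_um2")
  areas <- areas[stats::complete.cases(areas[, need]), ]
  if (nrow(areas) < 3L) stop_input("need >= 3 paired slice areas")
  if (stats::var(areas$tissue_area_um2) == 0)
    stop_input("explanatory slice areas are constant")
  fit <- stats::lm(ct_area_um2 ~ tissue_area_um2, data = areas)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       p = s$coefficients["tissue_area_um2", "Pr(>|t|)"])
}
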