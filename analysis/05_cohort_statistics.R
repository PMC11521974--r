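#!/usr/bin/env Rscript
# The study's statistical pathway on a synthetic cohort.
#
# Generates a per-ear cohort (10 ears per age x sex cell) with the aging
# effect structure the pipeline targets, then for every measurement:
# normality screen (Shapiro-Wilk + Kolmogorov-Smirnov), two-way age x sex
# ANOVA with interaction (Type III), and Bonferroni-corrected post-hoc
# comparisons among the four cells whenever the interaction is significant.

suppressPackageStartupMessages(library(otomorph))
dir.create("results", showWarnings = FALSE)

co <- gen_cohort(cohort_effects(n_per_cell = 10, seed = 314159))
write.csv(co, "results/cohort.csv", row.names = FALSE)

anova_rows <- list(); norm_rows <- list(); ph_rows <- list()
for (m in unique(co$measurement)) {
  ns <- normality_screen(co$value[co$measurement == m], warn = FALSE)
  norm_rows[[m]] <- data.frame(measurement = m, shapiro_p = ns$shapiro_p,
                               ks_p = ns$ks_p, pass = ns$pass)
  av <- two_way_anova(co, m)
  anova_rows[[m]] <- cbind(measurement = m, av$effects, n = av$n)
  inter_p <- av$effects$p[av$effects$effect == "interaction"]
  cat(sprintf("%-16s age p = %.4g, sex p = %.4g, interaction p = %.4g (n = %d)\n",
              m, av$effects$p[1], av$effects$p[2], inter_p, av$n))
  if (inter_p < 0.05) {
    ph <- bonferroni_posthoc(co, m)
    ph_rows[[m]] <- cbind(measurement = m, as.data.frame(ph))
    cat("  -> interaction significant; Bonferroni post-hoc written\n")
  }
}
write.csv(do.call(rbind, norm_rows), "results/normality.csv",
          row.names = FALSE)
write.csv(do.call(rbind, anova_rows), "results/anova.csv",
          row.names = FALSE)
if (length(ph_rows))
  write.csv(do.call(rbind, ph_rows), "results/posthoc.csv",
            row.names = FALSE)

cat("\nWith the default effect structure the age effect should reach",
    "significance for every measurement at n = 40 ears.\n")
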