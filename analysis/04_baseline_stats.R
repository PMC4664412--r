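#!/usr/bin/env Rscript
# Baseline group comparisons across the four AD subtypes: chi-square for
# categorical variables (gender, ApoE e4 carriage from the published
# counts), ANOVA/ANCOVA for the simulated continuous measures with
# education as covariate.

suppressPackageStartupMessages(library(adsubtype))

## Published categorical counts across BI/HA/CA/BS are fixed inputs
gender_tab <- rbind(female = c(41, 21, 10, 7), male = c(55, 10, 9, 10))
apoe_tab <- rbind(carrier = c(67, 21, 8, 9), noncarrier = c(29, 10, 11, 8))
res_gender <- chi_square_test(gender_tab)
res_apoe <- chi_square_test(apoe_tab)
cat(sprintf("Gender by subtype: chi-sq = %.2f, df = %d, p = %.3f\n",
            res_gender$statistic, res_gender$df, res_gender$p_value))
cat(sprintf("ApoE e4 by subtype: chi-sq = %.2f, df = %d, p = %.3f\n",
            res_apoe$statistic, res_apoe$df, res_apoe$p_value))

## Simulated baseline neuropsychological measures, education-adjusted
labels <- utils::read.csv("results/labels.csv")
long <- utils::read.csv("results/longitudinal.csv")
base <- merge(labels[c("subject_id", "subtype")],
              long[long$visit_time == 0, ], by = "subject_id")

rows <- list()
for (m in c("mmse", "adni_mem", "adni_ef")) {
  res <- ancova(base[[m]], base$subtype.x, base$education)
  cat(sprintf("%s ~ subtype + education: F = %.2f (df %d, %d), p = %.4g\n",
              m, res$statistic, res$df[1], res$df[2], res$p_value))
  av <- one_way_anova(base[[m]], base$subtype.x)
  sig <- av$post_hoc[av$post_hoc$p_adj < 0.05, ]
  if (nrow(sig) > 0) {
    cat(sprintf("  Tukey pairs p<0.05: %s\n",
                paste(sig$pair, collapse = ", ")))
  }
  rows[[m]] <- data.frame(variable = m, F = res$statistic,
                          df1 = res$df[1], df2 = res$df[2], p = res$p_value)
}
utils::write.csv(
  rbind(data.frame(variable = c("gender", "apoe_e4"),
                   F = c(res_gender$statistic, res_apoe$statistic),
                   df1 = c(res_gender$df, res_apoe$df), df2 = NA,
                   p = c(res_gender$p_value, res_apoe$p_value)),
        do.call(rbind, rows)),
  "results/baseline_comparisons.csv", row.names = FALSE
)
cat("Wrote results/baseline_comparisons.csv.\n")
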