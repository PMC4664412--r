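#!/usr/bin/env Rscript
# CSF biomarker comparisons: median (IQR) per group, Kruskal-Wallis
# across AD subtypes, pairwise Mann-Whitney vs CN, and amyloid
# positivity at the 192 pg/mL cutoff.

suppressPackageStartupMessages(library(adsubtype))

csf <- utils::read.csv("results/csf.csv")
labels <- utils::read.csv("results/labels.csv")
# replace latent labels with classified ones for the AD subjects
idx <- match(csf$subject_id, labels$subject_id)
csf$subtype <- ifelse(is.na(idx), csf$subtype, labels$subtype[idx])

groups <- c("CN", "BI", "HA", "CA", "BS")
markers <- c("abeta42", "t_tau", "p_tau", "t_tau_abeta_ratio",
             "p_tau_abeta_ratio")
rows <- list()
for (m in markers) {
  ad <- csf[csf$subtype != "CN", ]
  kw <- kruskal_wallis(split(ad[[m]], ad$subtype))
  cells <- vapply(groups, function(g) {
    q <- median_iqr(csf[[m]][csf$subtype == g])
    sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
  }, character(1))
  mw <- vapply(setdiff(groups, "CN"), function(g) {
    mann_whitney(csf[[m]][csf$subtype == g],
                 csf[[m]][csf$subtype == "CN"])$p_value
  }, numeric(1))
  cat(sprintf("%s: %s | KW across subtypes p = %.3f\n", m,
              paste(sprintf("%s %s", groups, cells), collapse = "; "),
              kw$p_value))
  rows[[m]] <- data.frame(biomarker = m, t(cells), kw_p = kw$p_value,
                          t(setNames(mw, paste0("mw_vs_cn_", names(mw)))))
}
utils::write.csv(do.call(rbind, rows), "results/csf_summary.csv",
                 row.names = FALSE)

pos <- classify_abeta_positive(csf$abeta42)
for (g in groups) {
  sel <- csf$subtype == g
  cat(sprintf("A-beta positive (<= 192 pg/mL) in %s: %d/%d (%.0f%%)\n",
              g, sum(pos[sel]), sum(sel), 100 * mean(pos[sel])))
}
cat("Wrote results/csf_summary.csv.\n")
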