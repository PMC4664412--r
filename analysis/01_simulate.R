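#!/usr/bin/env Rscript
# Simulate the study cohort: 222 cognitively normal (CN) and 163 AD
# subjects with FreeSurfer-style regional volumes, 2-year cognitive
# follow-up and CSF biomarkers. Writes the raw tables under results/.

suppressPackageStartupMessages(library(adsubtype))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- cohort_config(n_cn = 222, n_ad = 163, seed = 20)

cn <- generate_cn_cohort(cfg)
norm <- build_norm_table(cn, default_strata())
ad <- generate_ad_cohort(cfg, norm)
subjects <- rbind(cn, ad)
write_subjects(subjects, file.path(out_dir, "subjects.csv"))

long <- generate_longitudinal(subjects, cfg)
write_subjects(long, file.path(out_dir, "longitudinal.csv"))
csf <- generate_csf(subjects, cfg)
write_subjects(csf, file.path(out_dir, "csf.csv"))

cat(sprintf("Simulated %d CN and %d AD subjects (seed %d).\n",
            nrow(cn), nrow(ad), cfg$seed))
cat(sprintf("Latent AD subtype counts: %s.\n",
            paste(sprintf("%s %d", names(table(ad$true_subtype)),
                          table(ad$true_subtype)), collapse = ", ")))
cat(sprintf("Longitudinal rows: %d; CSF rows: %d.\n", nrow(long), nrow(csf)))
cat("Wrote subjects.csv, longitudinal.csv, csf.csv under results/.\n")
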