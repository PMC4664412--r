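#!/usr/bin/env Rscript
# Build the age- and gender-specific normative table of ICV-normalized
# regional volumes from the CN subjects, using four overlapping age
# strata (55-70, 65-80, 70-85, 75-90) per gender.

suppressPackageStartupMessages(library(adsubtype))

subjects <- read_subjects("results/subjects.csv")
cn <- subjects[subjects$diagnosis == "CN", ]
norm <- build_norm_table(cn, default_strata())
write_norm_table(norm, "results/norm_table.csv")

cat(sprintf("Built norm table from %d CN subjects: %d cells.\n",
            nrow(cn), nrow(norm)))
cells <- unique(norm[c("stratum", "gender", "n")])
for (i in seq_len(nrow(cells))) {
  cat(sprintf("  stratum %d, %s: n = %d\n", cells$stratum[i],
              cells$gender[i], cells$n[i]))
}
cat("Wrote results/norm_table.csv (+ .json stratification sidecar).\n")
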