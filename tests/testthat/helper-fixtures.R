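# Shared fixture builders. Everything is generated in code; no data files.

# A deterministic CN cohort with a known linear age trend, built without
# the package generator so normative-module tests do not depend on it.
make_cn_grid <- function(n = 400, seed = 101,
                         intercepts = c(hippocampal = 0.0046,
                                        frontal = 0.0250,
                                        temporal = 0.0135,
                                        parietal = 0.0160),
                         slopes = c(hippocampal = -1.5e-5, frontal = -5e-5,
                                    temporal = -2e-5, parietal = -3e-5),
                         sds = c(hippocampal = 0.00045, frontal = 0.0020,
                                 temporal = 0.0012, parietal = 0.0016)) {
  set.seed(seed)
  age <- runif(n, 55, 90)
  gender <- rep(c("female", "male"), length.out = n)
  icv <- ifelse(gender == "male", 1.55e6, 1.38e6) + rnorm(n, 0, 1e5)
  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, gender = gender, diagnosis = "CN", icv_mm3 = icv,
    stringsAsFactors = FALSE
  )
  for (roi in names(intercepts)) {
    ratio <- intercepts[roi] + slopes[roi] * (age - 55) + rnorm(n, 0, sds[roi])
    out[[paste0(roi, "_mm3")]] <- ratio * icv
  }
  out
}

# Four equal-width strata covering 55-90 whose nearest-midpoint partition
# coincides with interval membership, so each subject contributes to
# exactly one norm cell (needed for the self-standardization identity).
non_overlapping_strata <- function(min_stratum_n = 10) {
  b <- seq(55, 90, length.out = 5)
  strata_spec(b[1:4], b[2:5], min_stratum_n = min_stratum_n)
}

# Literal transcription of the classification rule table, used as an
# independent oracle for the vectorized classifier.
classify_oracle <- function(z, cutoff = -1.0) {
  hip <- z[1] < cutoff
  cort <- any(z[2:4] < cutoff)
  if (hip && cort) "BI" else if (hip) "HA" else if (cort) "CA" else "BS"
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# long cognitive-score panel with known per-subtype annual slopes
make_long_panel <- function(n_per_group, slopes, resid_sd = 1,
                            intercept_sd = 1, seed = 1,
                            baselines = c(BI = 23, HA = 23.5, CA = 23.5,
                                          BS = 24.5)) {
  set.seed(seed)
  groups <- names(slopes)
  n <- n_per_group * length(groups)
  subtype <- rep(groups, each = n_per_group)
  id <- sprintf("L%04d", seq_len(n))
  edu <- round(rnorm(n, 15, 3))
  b_i <- rnorm(n, 0, intercept_sd)
  long <- expand.grid(row = seq_len(n), visit_time = 0:2)
  long$subject_id <- id[long$row]
  long$subtype <- subtype[long$row]
  long$education <- edu[long$row]
  long$score <- baselines[long$subtype] + b_i[long$row] +
    slopes[long$subtype] * long$visit_time +
    rnorm(nrow(long), 0, resid_sd)
  long[c("subject_id", "subtype", "education", "visit_time", "score")]
}
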