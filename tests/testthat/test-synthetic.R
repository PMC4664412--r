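test_that("generation is seeded and handles the empty cohort", {
  cfg <- cohort_config(n_cn = 40, n_ad = 30, seed = 5)
  expect_identical(generate_cn_cohort(cfg), generate_cn_cohort(cfg))
  expect_equal(nrow(generate_cn_cohort(cfg, n = 0)), 0)

  cn <- generate_cn_cohort(cohort_config(n_cn = 200, seed = 5))
  norm <- build_norm_table(cn, default_strata(min_stratum_n = 5))
  cfg2 <- cohort_config(n_cn = 200, n_ad = 50, seed = 5)
  expect_identical(generate_ad_cohort(cfg2, norm), generate_ad_cohort(cfg2, norm))
})

test_that("invalid configurations are refused", {
  expect_error(cohort_config(n_cn = -1), class = "adsubtype_config_error")
  expect_error(cohort_config(age_range = c(70, 60)),
               class = "adsubtype_config_error")
  expect_error(cohort_config(age_range = c(50, 90)),
               class = "adsubtype_config_error")
  expect_error(cohort_config(subtype_mixture = c(BI = 0.5, HA = 0.5,
                                                 CA = 0.5, BS = 0.5)),
               class = "adsubtype_config_error")
  expect_error(cohort_config(z_noise_sd = -1), class = "adsubtype_config_error")
  bad_icv <- data.frame(gender = c("female", "male"), mean = c(-1, 1.5e6),
                        sd = c(1e5, 1e5))
  expect_error(cohort_config(icv_params = bad_icv),
               class = "adsubtype_config_error")
  lp <- adsubtype:::default_longitudinal_params()
  lp$dropout <- -0.1
  expect_error(cohort_config(longitudinal = lp),
               class = "adsubtype_config_error")
  csf <- adsubtype:::default_csf_params()
  csf$abeta42$median[1] <- 0
  expect_error(cohort_config(csf_params = csf),
               class = "adsubtype_config_error")
})

test_that("CN normalized volumes regress on age with the configured slope", {
  cfg <- cohort_config(n_cn = 5000, seed = 13)
  cn <- generate_cn_cohort(cfg)
  ratio <- cn$hippocampal_mm3 / cn$icv_mm3
  fit <- summary(lm(ratio ~ cn$age))
  est <- fit$coefficients["cn$age", ]
  expect_lt(abs(est["Estimate"] - (-1.5e-5)), 2 * est["Std. Error"])
  # ages uniform over the configured range
  expect_gte(min(cn$age), 55)
  expect_lte(max(cn$age), 90)
})

test_that("single-subtype mixtures produce the configured Z structure", {
  cfg_cn <- cohort_config(n_cn = 1500, seed = 17)
  cn <- generate_cn_cohort(cfg_cn)
  norm <- build_norm_table(cn, default_strata())

  # pure-BI mixture with the reported BI effects classifies >= 90% BI
  cfg_bi <- cohort_config(n_cn = 1500, n_ad = 1000, seed = 17,
                          subtype_mixture = c(BI = 1, HA = 0, CA = 0, BS = 0))
  ad <- generate_ad_cohort(cfg_bi, norm)
  z <- classify_profiles(compute_z_profiles(ad, norm))
  expect_gte(mean(z$subtype == "BI"), 0.90)

  # null effects: mean Z-profile within +-0.1 of zero
  zero_fx <- adsubtype:::default_z_effects() * 0
  cfg_null <- cohort_config(n_cn = 1500, n_ad = 2000, seed = 17,
                            subtype_mixture = c(BI = 0, HA = 0, CA = 0, BS = 1),
                            subtype_z_effects = zero_fx)
  ad0 <- generate_ad_cohort(cfg_null, norm)
  z0 <- compute_z_profiles(ad0, norm)
  for (col in c("z_h", "z_f", "z_t", "z_p")) {
    expect_lt(abs(mean(z0[[col]])), 0.1)
  }
})

test_that("latent labels follow the configured mixture", {
  cfg <- cohort_config(n_cn = 1000, n_ad = 163, seed = 19)
  cn <- generate_cn_cohort(cfg)
  norm <- build_norm_table(cn, default_strata())
  ad <- generate_ad_cohort(cfg, norm)
  expect_equal(nrow(ad), 163)
  expect_true(all(ad$true_subtype %in% c("BI", "HA", "CA", "BS")))

  big <- generate_ad_cohort(cohort_config(n_cn = 1000, n_ad = 5000, seed = 19),
                            norm)
  p_hat <- prop.table(table(factor(big$true_subtype,
                                   levels = c("BI", "HA", "CA", "BS"))))
  mix <- cfg$subtype_mixture
  se <- sqrt(mix * (1 - mix) / 5000)
  expect_true(all(abs(p_hat - mix) <= 3 * se))
})

test_that("empirical label confusion matches the analytic orthant formula", {
  cfg <- cohort_config(n_cn = 1500, n_ad = 4000, seed = 43)
  cn <- generate_cn_cohort(cfg)
  norm <- build_norm_table(cn, default_strata())
  ad <- generate_ad_cohort(cfg, norm)
  z <- classify_profiles(compute_z_profiles(ad, norm))
  M <- subtype_confusion_matrix(cfg$subtype_z_effects, cfg$z_noise_sd)
  expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
  emp <- prop.table(table(factor(ad$true_subtype, levels = rownames(M)),
                          factor(z$subtype, levels = colnames(M))), 1)
  for (i in rownames(M)) {
    n_i <- sum(ad$true_subtype == i)
    se <- sqrt(pmax(M[i, ] * (1 - M[i, ]), 1e-12) / n_i)
    expect_true(all(abs(emp[i, ] - M[i, ]) <= 3 * se + 0.01))
  }
})

test_that("norm tables missing a needed stratum stop AD generation", {
  cn <- make_cn_grid(300)
  cn <- cn[cn$age <= 70, ]
  narrow <- build_norm_table(cn, strata_spec(55, 70, min_stratum_n = 5))
  cfg <- cohort_config(n_cn = 300, n_ad = 50, seed = 3)
  expect_error(generate_ad_cohort(cfg, narrow),
               class = "adsubtype_generation_error")
})

test_that("longitudinal scores have the configured mean structure", {
  cfg <- cohort_config(n_cn = 50, n_ad = 50, seed = 23)
  # degenerate variances: the three visits repeat the baseline mean exactly
  lp <- cfg$longitudinal
  lp$slopes[] <- 0
  lp$resid_sd[] <- 0
  lp$intercept_sd[] <- 0
  cfg0 <- cohort_config(n_cn = 50, n_ad = 50, seed = 23, longitudinal = lp)
  cn <- generate_cn_cohort(cfg0)
  long0 <- generate_longitudinal(cn, cfg0)
  spread <- tapply(long0$mmse, long0$subject_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_equal(unique(long0$mmse), 29.11)

  # every subject has exactly three visits when dropout is 0
  expect_equal(as.integer(table(table(long0$subject_id))), 50)
  expect_equal(sort(unique(long0$visit_time)), c(0, 1, 2))

  # configured slope ordering shows in large-sample 2-year change
  set.seed(23)
  subj <- data.frame(subject_id = sprintf("A%04d", 1:2000),
                     education = 15,
                     true_subtype = sample(c("CA", "BS"), 2000, replace = TRUE),
                     stringsAsFactors = FALSE)
  long <- generate_longitudinal(subj, cfg)
  chg <- function(g) {
    d <- long[long$subtype == g, ]
    mean(d$mmse[d$visit_time == 2]) - mean(d$mmse[d$visit_time == 0])
  }
  expect_lt(chg("CA"), chg("BS"))
})

test_that("dropout removes follow-up visits only", {
  cfg <- cohort_config(n_cn = 200, seed = 29)
  lp <- cfg$longitudinal
  lp$dropout <- 0.4
  cfg_d <- cohort_config(n_cn = 200, seed = 29, longitudinal = lp)
  cn <- generate_cn_cohort(cfg_d)
  long <- generate_longitudinal(cn, cfg_d)
  expect_equal(sum(long$visit_time == 0), 200)
  expect_lt(sum(long$visit_time > 0), 2 * 200)
})

test_that("CSF draws reproduce the configured medians and are seeded", {
  cfg <- cohort_config(seed = 31)
  subj <- data.frame(subject_id = sprintf("B%04d", 1:5000),
                     true_subtype = "BI", stringsAsFactors = FALSE)
  csf <- generate_csf(subj, cfg)
  expect_identical(csf, generate_csf(subj, cfg))
  expect_gt(median(csf$abeta42), 125)
  expect_lt(median(csf$abeta42), 137)
  expect_equal(csf$t_tau_abeta_ratio, csf$t_tau / csf$abeta42)

  # CN median 216 > 192, so fewer than half the draws fall at/below 192
  subj_cn <- data.frame(subject_id = sprintf("C%04d", 1:5000),
                        true_subtype = "CN", stringsAsFactors = FALSE)
  csf_cn <- generate_csf(subj_cn, cfg)
  expect_lt(mean(classify_abeta_positive(csf_cn$abeta42)), 0.5)
})
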