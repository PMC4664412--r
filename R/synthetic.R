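# Synthetic ADNI-like cohort generator. The real analysis cohort is
# access-controlled, so every downstream stage is exercised on simulated
# subjects carrying the same statistical structure the pipeline assumes:
# age- and gender-dependent head size, age-declining normalized regional
# volumes in cognitively normal subjects, a four-subtype AD mixture with
# configurable mean Z-profiles, subtype-dependent cognitive decline and
# log-skewed CSF biomarker distributions.

default_roi_baseline <- function() {
  # intercept = normalized volume at age 55; linear decline per year;
  # residual SD. Values chosen so that CN means near age 75 sit close to
  # the normalized volumes observed in atrophy-spared subjects.
  data.frame(
    roi = ROI_NAMES,
    intercept = c(0.0046, 0.0250, 0.0135, 0.0160),
    slope = c(-1.5e-5, -5e-5, -2e-5, -3e-5),
    resid_sd = c(0.00045, 0.0020, 0.0012, 0.0016),
    stringsAsFactors = FALSE
  )
}

default_z_effects <- function() {
  # per-subtype mean Z-profiles (rows BI, HA, CA, BS; cols H, F, T, P)
  matrix(
    c(-2.20, -1.05, -1.38, -1.52,
      -2.13, -0.04, -0.22, -0.21,
      -0.20, -1.40, -1.06, -1.92,
      -0.15,  0.24,  0.14,  0.23),
    nrow = 4, byrow = TRUE,
    dimnames = list(SUBTYPE_LEVELS, ROI_NAMES)
  )
}

default_longitudinal_params <- function() {
  groups <- c("CN", SUBTYPE_LEVELS)
  list(
    measures = c("mmse", "adni_mem", "adni_ef"),
    baseline_means = matrix(
      c(29.11,  0.97,  0.70,
        23.07, -0.91, -0.98,
        23.42, -0.74, -0.50,
        23.58, -0.64, -1.31,
        24.41, -0.45, -0.53),
      nrow = 5, byrow = TRUE,
      dimnames = list(groups, c("mmse", "adni_mem", "adni_ef"))
    ),
    # annual change; ordering CA fastest, BS slowest decline
    slopes = matrix(
      c(-0.10, -0.02, -0.02,
        -2.00, -0.35, -0.40,
        -1.40, -0.25, -0.28,
        -2.80, -0.45, -0.60,
        -0.70, -0.12, -0.15),
      nrow = 5, byrow = TRUE,
      dimnames = list(groups, c("mmse", "adni_mem", "adni_ef"))
    ),
    resid_sd = c(mmse = 2.0, adni_mem = 0.5, adni_ef = 0.85),
    intercept_sd = c(mmse = 1.5, adni_mem = 0.4, adni_ef = 0.6),
    dropout = 0
  )
}

default_csf_params <- function() {
  # per-group median and quartiles (pg/mL); sampled log-normally so the
  # configured median and IQR are reproduced on the natural scale
  groups <- c("CN", SUBTYPE_LEVELS)
  list(
    abeta42 = data.frame(group = groups,
                         median = c(216, 131, 138, 151, 135),
                         q25 = c(158, 116, 127, 138, 122),
                         q75 = c(253, 153, 166, 178, 212)),
    t_tau = data.frame(group = groups,
                       median = c(61, 129, 120, 114, 58),
                       q25 = c(47, 72, 94, 78, 47),
                       q75 = c(85, 160, 152, 189, 109)),
    p_tau = data.frame(group = groups,
                       median = c(20, 39, 39, 34, 24),
                       q25 = c(16, 31, 31, 26, 14),
                       q75 = c(30, 57, 56, 55, 38))
  )
}

#' Analytic label-confusion matrix of the generator-classifier loop
#'
#' Under the generator's noise model the four Z-scores of a subject with
#' latent subtype `i` are independent normals centred at that subtype's
#' mean Z-vector with SD `z_noise_sd`, so the probability of being
#' *classified* as subtype `j` is a product of normal orthant
#' probabilities. Row `i`, column `j` gives P(classified j | latent i).
#' The expected classified mixture is `mixture %*% confusion`; with the
#' default dispersion the off-diagonal leakage is small enough that the
#' classified mixture stays within a fraction of a binomial standard
#' error of the configured one at the cohort sizes used here.
#'
#' @param z_effects 4x4 matrix of per-subtype mean Z (rows BI/HA/CA/BS).
#' @param z_noise_sd within-subtype SD of the injected Z-scores.
#' @param cutoff classification cutoff on the Z scale.
#' @return 4x4 row-stochastic matrix.
#' @export
subtype_confusion_matrix <- function(z_effects = default_z_effects(),
                                     z_noise_sd = 0.35, cutoff = -1.0) {
  M <- matrix(0, 4, 4, dimnames = list(SUBTYPE_LEVELS, SUBTYPE_LEVELS))
  for (i in SUBTYPE_LEVELS) {
    # P(z < cutoff) per ROI for this latent subtype
    p_below <- stats::pnorm(cutoff, mean = z_effects[i, ], sd = z_noise_sd)
    p_hip <- p_below[1]
    p_cort_spared <- prod(1 - p_below[2:4])  # all three cortical >= cutoff
    M[i, "BI"] <- p_hip * (1 - p_cort_spared)
    M[i, "HA"] <- p_hip * p_cort_spared
    M[i, "CA"] <- (1 - p_hip) * (1 - p_cort_spared)
    M[i, "BS"] <- (1 - p_hip) * p_cort_spared
  }
  M
}

#' Configuration for the synthetic cohort generator
#'
#' All defaults are fixed study conditions: cohort sizes 222 CN / 163 AD,
#' ages uniform on 55-90, the default subtype mixture
#' (58.9/19.0/11.7/10.4%), per-subtype mean Z-profiles, CSF medians and
#' IQRs matching the reported group summaries, and gender-dependent ICV
#' creating a genuine head-size confound for the norm machinery to remove.
#'
#' @param n_cn,n_ad cohort sizes.
#' @param seed integer seed; each generator draws from a deterministic
#'   stream derived from it.
#' @param age_range inclusive age bounds in years, within \[55, 90\].
#' @param female_fraction proportion of female subjects.
#' @param icv_params data frame `gender`, `mean`, `sd` of intracranial
#'   volume in mm^3.
#' @param roi_baseline data frame `roi`, `intercept`, `slope`, `resid_sd`
#'   for CN normalized volumes (intercept at age 55, slope per year).
#' @param subtype_mixture named numeric, proportions of BI/HA/CA/BS,
#'   summing to 1.
#' @param subtype_z_effects 4x4 matrix of target mean Z per subtype (rows)
#'   and ROI (columns).
#' @param z_noise_sd within-subtype SD of the injected Z-scores; the
#'   default keeps the classifier's boundary leakage small, so the
#'   expected classified mixture matches the configured one (see
#'   [subtype_confusion_matrix()]).
#' @param longitudinal list: `baseline_means`, `slopes` (group x measure
#'   matrices), `resid_sd`, `intercept_sd` (per measure), `dropout`
#'   (per-visit missingness probability at follow-up).
#' @param csf_params per-marker data frames of group medians and quartiles.
#' @param education_mean named per-group mean years of education.
#' @param education_sd SD of education years.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_cn = 222, n_ad = 163, seed = 1,
                          age_range = c(55, 90), female_fraction = 0.48,
                          icv_params = data.frame(
                            gender = c("female", "male"),
                            mean = c(1.38e6, 1.55e6),
                            sd = c(1.1e5, 1.2e5)),
                          roi_baseline = default_roi_baseline(),
                          subtype_mixture = c(BI = 0.589, HA = 0.190,
                                              CA = 0.117, BS = 0.104),
                          subtype_z_effects = default_z_effects(),
                          z_noise_sd = 0.35,
                          longitudinal = default_longitudinal_params(),
                          csf_params = default_csf_params(),
                          education_mean = c(CN = 16.1, BI = 15.0, HA = 13.5,
                                             CA = 16.1, BS = 14.0),
                          education_sd = 2.9) {
  if (n_cn < 0 || n_ad < 0) {
    stop_adsubtype("cohort sizes must be non-negative",
                   "adsubtype_config_error")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] < 55 || age_range[2] > 90) {
    stop_adsubtype("age_range must be an increasing pair within [55, 90]",
                   "adsubtype_config_error")
  }
  if (female_fraction < 0 || female_fraction > 1) {
    stop_adsubtype("female_fraction must be in [0, 1]",
                   "adsubtype_config_error")
  }
  if (any(icv_params$mean <= 0) || any(icv_params$sd < 0)) {
    stop_adsubtype("ICV means must be > 0 and SDs >= 0",
                   "adsubtype_config_error")
  }
  if (any(roi_baseline$resid_sd < 0)) {
    stop_adsubtype("ROI residual SDs must be >= 0", "adsubtype_config_error")
  }
  if (any(subtype_mixture < 0) ||
      abs(sum(subtype_mixture) - 1) > 1e-9 ||
      !identical(names(subtype_mixture), SUBTYPE_LEVELS)) {
    stop_adsubtype(
      "subtype_mixture must be named BI/HA/CA/BS, non-negative, summing to 1",
      "adsubtype_config_error"
    )
  }
  if (z_noise_sd < 0) {
    stop_adsubtype("z_noise_sd must be >= 0", "adsubtype_config_error")
  }
  if (longitudinal$dropout < 0 || longitudinal$dropout > 1) {
    stop_adsubtype("dropout probability must be in [0, 1]",
                   "adsubtype_config_error")
  }
  for (marker in names(csf_params)) {
    p <- csf_params[[marker]]
    if (any(p$median <= 0) || any(p$q25 <= 0) || any(p$q75 < p$q25)) {
      stop_adsubtype(sprintf("invalid CSF parameters for %s", marker),
                     "adsubtype_config_error")
    }
  }
  structure(
    list(n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
         seed = as.integer(seed), age_range = age_range,
         female_fraction = female_fraction, icv_params = icv_params,
         roi_baseline = roi_baseline, subtype_mixture = subtype_mixture,
         subtype_z_effects = subtype_z_effects, z_noise_sd = z_noise_sd,
         longitudinal = longitudinal, csf_params = csf_params,
         education_mean = education_mean, education_sd = education_sd),
    class = "cohort_config"
  )
}

draw_demographics <- function(config, n, prefix, groups) {
  gender <- ifelse(stats::runif(n) < config$female_fraction,
                   "female", "male")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  icv <- numeric(n)
  for (g in unique(gender)) {
    row <- config$icv_params[config$icv_params$gender == g, ]
    idx <- gender == g
    icv[idx] <- stats::rnorm(sum(idx), row$mean, row$sd)
  }
  edu <- round(stats::rnorm(n, config$education_mean[groups],
                            config$education_sd))
  data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = age, gender = gender,
    education = pmin(pmax(edu, 6), 20),
    icv_mm3 = icv,
    stringsAsFactors = FALSE
  )
}

#' Generate a cognitively normal cohort
#'
#' Ages are uniform over the configured range; ICV is gender-dependent
#' normal; each normalized ROI volume follows a linear age trend
#' `intercept + slope * (age - 55)` plus Gaussian noise, and the raw volume
#' is the normalized volume multiplied back by the subject's ICV.
#' Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param n number of subjects; defaults to `config$n_cn`.
#' @return subject data frame (schema of [read_subjects()]) with extra
#'   columns `education` and `true_subtype = "CN"`.
#' @export
generate_cn_cohort <- function(config, n = config$n_cn) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  if (n == 0) return(empty_cohort())
  demo <- draw_demographics(config, n, "CN", rep("CN", n))
  out <- data.frame(demo[1:2], gender = demo$gender, diagnosis = "CN",
                    education = demo$education, icv_mm3 = demo$icv_mm3,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ROI_NAMES)) {
    b <- config$roi_baseline[i, ]
    ratio <- b$intercept + b$slope * (demo$age - 55) +
      stats::rnorm(n, 0, b$resid_sd)
    out[[paste0(ROI_NAMES[i], "_mm3")]] <- ratio * demo$icv_mm3
  }
  out$true_subtype <- "CN"
  out
}

empty_cohort <- function() {
  cols <- c("subject_id", "age", "gender", "diagnosis", "education",
            "icv_mm3", paste0(ROI_NAMES, "_mm3"), "true_subtype")
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  for (col in setdiff(cols, c("subject_id", "gender", "diagnosis",
                              "true_subtype"))) {
    out[[col]] <- numeric(0)
  }
  out
}

#' Generate an AD cohort with latent atrophy subtypes
#'
#' Each subject draws a latent subtype from the configured mixture. Its
#' normalized volumes are injected *relative to the supplied empirical norm
#' table*: `ratio = cell_mean + z * cell_sd` with
#' `z ~ N(mean Z of the subtype, z_noise_sd)`, so the expected Z-profile of
#' each latent class equals the configured effect vector by construction.
#' Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param norm a `norm_table` built from a CN cohort of the same
#'   configuration family.
#' @param n number of AD subjects; defaults to `config$n_ad`.
#' @return subject data frame with `true_subtype` in BI/HA/CA/BS.
#' @export
generate_ad_cohort <- function(config, norm, n = config$n_ad) {
  stopifnot(inherits(config, "cohort_config"), inherits(norm, "norm_table"))
  spec <- attr(norm, "strata_spec")
  set.seed(config$seed + 1L)
  if (n == 0) return(empty_cohort())
  subtype <- sample(SUBTYPE_LEVELS, n, replace = TRUE,
                    prob = config$subtype_mixture)
  demo <- draw_demographics(config, n, "AD", subtype)
  stratum <- tryCatch(
    assign_stratum(demo$age, spec),
    adsubtype_range_error = function(e) {
      stop_adsubtype(
        paste("norm table does not cover generated ages:",
              conditionMessage(e)),
        "adsubtype_generation_error"
      )
    }
  )
  out <- data.frame(demo[1:2], gender = demo$gender, diagnosis = "AD",
                    education = demo$education, icv_mm3 = demo$icv_mm3,
                    stringsAsFactors = FALSE)
  for (roi in ROI_NAMES) {
    z <- config$subtype_z_effects[subtype, roi] +
      stats::rnorm(n, 0, config$z_noise_sd)
    ratio <- numeric(n)
    for (s in unique(stratum)) {
      for (g in unique(demo$gender)) {
        idx <- which(stratum == s & demo$gender == g)
        if (length(idx) == 0) next
        cell <- tryCatch(
          norm_cell(norm, s, g, roi),
          adsubtype_lookup_error = function(e) {
            stop_adsubtype(conditionMessage(e), "adsubtype_generation_error")
          }
        )
        ratio[idx] <- cell$mean + z[idx] * cell$sd
      }
    }
    out[[paste0(roi, "_mm3")]] <- pmax(ratio, 0) * demo$icv_mm3
  }
  out$true_subtype <- subtype
  out
}

#' Generate 2-year longitudinal cognitive scores
#'
#' For each subject and measure, scores at 0/1/2 years follow
#' `baseline_mean(group) + random_intercept + slope(group) * t + noise`.
#' Follow-up visits can be dropped missing-at-random with the configured
#' per-visit probability; baseline is always observed. Deterministic given
#' `config$seed`.
#'
#' @param subjects subject data frame carrying a `true_subtype` (or
#'   `subtype`) column with values in CN/BI/HA/CA/BS.
#' @param config a [cohort_config()].
#' @return long data frame: `subject_id`, `subtype`, `education`,
#'   `visit_time` (years), `mmse`, `adni_mem`, `adni_ef`.
#' @export
generate_longitudinal <- function(subjects, config) {
  stopifnot(inherits(config, "cohort_config"))
  lp <- config$longitudinal
  group <- if ("true_subtype" %in% names(subjects)) subjects$true_subtype
           else subjects$subtype
  if (is.null(group) || any(!group %in% rownames(lp$baseline_means))) {
    stop_adsubtype("subjects must carry subtype labels (CN/BI/HA/CA/BS)",
                   "adsubtype_validation_error")
  }
  set.seed(config$seed + 2L)
  n <- nrow(subjects)
  times <- c(0, 1, 2)
  long <- data.frame(
    subject_id = rep(subjects$subject_id, each = length(times)),
    subtype = rep(as.character(group), each = length(times)),
    education = rep(subjects$education, each = length(times)),
    visit_time = rep(times, n),
    stringsAsFactors = FALSE
  )
  for (m in lp$measures) {
    b_i <- rep(stats::rnorm(n, 0, lp$intercept_sd[m]), each = length(times))
    long[[m]] <- lp$baseline_means[long$subtype, m] + b_i +
      lp$slopes[long$subtype, m] * long$visit_time +
      stats::rnorm(nrow(long), 0, lp$resid_sd[m])
  }
  if (lp$dropout > 0) {
    keep <- long$visit_time == 0 | stats::runif(nrow(long)) >= lp$dropout
    long <- long[keep, , drop = FALSE]
    rownames(long) <- NULL
  }
  long
}

#' Generate CSF biomarker records
#'
#' A-beta 1-42, t-tau and p-tau are drawn log-normally per subject group,
#' parameterised so that the configured group median and IQR are reproduced
#' on the natural (pg/mL) scale: `meanlog = log(median)`,
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`. Tau/A-beta ratios are
#' per-subject quotients. Deterministic given `config$seed`.
#'
#' @inheritParams generate_longitudinal
#' @return data frame: `subject_id`, `subtype`, `abeta42`, `t_tau`, `p_tau`,
#'   `t_tau_abeta_ratio`, `p_tau_abeta_ratio`.
#' @export
generate_csf <- function(subjects, config) {
  stopifnot(inherits(config, "cohort_config"))
  group <- if ("true_subtype" %in% names(subjects)) subjects$true_subtype
           else subjects$subtype
  if (is.null(group) ||
      any(!group %in% config$csf_params$abeta42$group)) {
    stop_adsubtype("subjects must carry subtype labels (CN/BI/HA/CA/BS)",
                   "adsubtype_validation_error")
  }
  set.seed(config$seed + 3L)
  n <- nrow(subjects)
  out <- data.frame(subject_id = subjects$subject_id,
                    subtype = as.character(group),
                    stringsAsFactors = FALSE)
  for (marker in c("abeta42", "t_tau", "p_tau")) {
    p <- config$csf_params[[marker]]
    rownames(p) <- p$group
    sdlog <- log(p[group, "q75"] / p[group, "q25"]) /
      (2 * stats::qnorm(0.75))
    out[[marker]] <- stats::rlnorm(n, meanlog = log(p[group, "median"]),
                                   sdlog = sdlog)
  }
  out$t_tau_abeta_ratio <- out$t_tau / out$abeta42
  out$p_tau_abeta_ratio <- out$p_tau / out$abeta42
  out
}
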