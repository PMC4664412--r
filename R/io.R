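# Table schemas and pipeline orchestration. All tables are plain CSV,
# UTF-8, "." decimal; numeric columns are written at full double precision
# so write/read round trips are lossless.

SUBJECT_COLUMNS <- c("subject_id", "age", "gender", "diagnosis", "icv_mm3",
                     "hippocampal_mm3", "frontal_mm3", "temporal_mm3",
                     "parietal_mm3")

#' Read a baseline subject table
#'
#' Expects a CSV with header `subject_id, age, gender, diagnosis, icv_mm3,
#' hippocampal_mm3, frontal_mm3, temporal_mm3, parietal_mm3` (ROI volumes
#' are bilateral sums in mm^3); extra columns are carried through. Rows
#' violating the record invariants (non-positive ICV, negative ROI volume,
#' ROI volume not below ICV, unknown gender/diagnosis, non-numeric fields)
#' are rejected with a warning naming the offending rows; valid rows are
#' returned.
#'
#' @param path CSV file path.
#' @return validated subject data frame.
#' @export
read_subjects <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_adsubtype(paste("subject table missing column(s):",
                         paste(missing_cols, collapse = ", ")),
                   "adsubtype_schema_error")
  }
  num_cols <- setdiff(SUBJECT_COLUMNS, c("subject_id", "gender", "diagnosis"))
  for (col in num_cols) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  gender <- tolower(trimws(raw$gender))
  gender[gender == "f"] <- "female"
  gender[gender == "m"] <- "male"
  raw$gender <- gender
  raw$diagnosis <- toupper(trimws(raw$diagnosis))
  roi_cols <- paste0(ROI_NAMES, "_mm3")
  bad <- !is.finite(raw$age) |
    !raw$gender %in% GENDER_LEVELS |
    !raw$diagnosis %in% c("CN", "AD") |
    !is.finite(raw$icv_mm3) | raw$icv_mm3 <= 0
  for (col in roi_cols) {
    bad <- bad | !is.finite(raw[[col]]) | raw[[col]] < 0 |
      raw[[col]] >= raw$icv_mm3
  }
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning(sprintf("rejected %d invalid row(s): %s", sum(bad),
                    paste(utils::head(which(bad), 10), collapse = ", ")))
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a subject table at full precision
#'
#' @param subjects subject data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  out <- subjects
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply quality-control exclusions to a subject table
#'
#' Removes subjects whose scans failed QC (e.g. poor segmentation quality)
#' and reports per-diagnosis counts before and after.
#'
#' @param subjects subject data frame.
#' @param exclude_ids subject IDs to drop.
#' @return the filtered data frame, with attribute `qc_counts`: a data
#'   frame of per-diagnosis `n_before`, `n_excluded`, `n_after`.
#' @export
apply_qc_exclusions <- function(subjects, exclude_ids) {
  drop <- subjects$subject_id %in% exclude_ids
  before <- table(factor(subjects$diagnosis, levels = c("CN", "AD")))
  excl <- table(factor(subjects$diagnosis[drop], levels = c("CN", "AD")))
  out <- subjects[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_counts") <- data.frame(
    diagnosis = c("CN", "AD"),
    n_before = as.integer(before),
    n_excluded = as.integer(excl),
    n_after = as.integer(before - excl),
    stringsAsFactors = FALSE
  )
  out
}

table3_style_summary <- function(subjects_ad, zlabels, longitudinal) {
  base <- longitudinal[longitudinal$visit_time == 0, ]
  merged <- merge(zlabels[, c("subject_id", "subtype")],
                  base, by = "subject_id")
  rows <- list()
  for (m in c("mmse", "adni_mem", "adni_ef")) {
    res <- ancova(merged[[m]], merged$subtype.x, merged$education)
    means <- tapply(merged[[m]], merged$subtype.x, mean)
    sds <- tapply(merged[[m]], merged$subtype.x, stats::sd)
    rows[[m]] <- data.frame(
      variable = m,
      t(setNames(sprintf("%.2f (%.2f)", means[SUBTYPE_LEVELS],
                         sds[SUBTYPE_LEVELS]), SUBTYPE_LEVELS)),
      test = res$test, statistic = res$statistic, p = res$p_value,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

csf_style_summary <- function(csf, abeta_cutoff = 192) {
  groups <- c("CN", SUBTYPE_LEVELS)
  markers <- c("abeta42", "t_tau", "p_tau", "t_tau_abeta_ratio",
               "p_tau_abeta_ratio")
  rows <- list()
  ad <- csf[csf$subtype != "CN", ]
  for (m in markers) {
    cells <- vapply(groups, function(g) {
      x <- csf[[m]][csf$subtype == g]
      if (length(x) == 0) return(NA_character_)
      q <- median_iqr(x)
      sprintf("%.3g (%.3g-%.3g)", q["median"], q["q25"], q["q75"])
    }, character(1))
    kw <- kruskal_wallis(split(ad[[m]], ad$subtype))
    cn_x <- csf[[m]][csf$subtype == "CN"]
    mw_p <- vapply(SUBTYPE_LEVELS, function(g) {
      mann_whitney(csf[[m]][csf$subtype == g], cn_x)$p_value
    }, numeric(1))
    rows[[m]] <- data.frame(
      biomarker = m, t(cells), kw_p_subtypes = kw$p_value,
      t(setNames(mw_p, paste0("mw_p_", SUBTYPE_LEVELS, "_vs_CN"))),
      stringsAsFactors = FALSE
    )
  }
  summary_tab <- do.call(rbind, rows)
  pos <- tapply(classify_abeta_positive(csf$abeta42, abeta_cutoff),
                factor(csf$subtype, levels = groups), sum)
  attr(summary_tab, "abeta_positive") <- data.frame(
    group = groups, n_positive = as.integer(pos),
    n = as.integer(table(factor(csf$subtype, levels = groups))),
    stringsAsFactors = FALSE
  )
  summary_tab
}

#' Run the full synthetic pipeline
#'
#' Chains simulate -> build norms -> Z-score -> classify -> frequency table
#' -> baseline group comparisons -> CSF summaries -> longitudinal mixed
#' models, writing every table as CSV under `out_dir` together with a run
#' log (seed, configuration digest, per-stage row counts). Deterministic
#' given the configuration seed: a rerun writes byte-identical CSVs.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory, created if absent.
#' @param spec a [strata_spec()] for the norm table.
#' @return invisibly, a list with all intermediate objects (`cn`, `ad`,
#'   `norm`, `labels`, `frequencies`, `baseline`, `csf_summary`, `lmm`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         spec = default_strata()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_adsubtype(sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e)),
                     "adsubtype_pipeline_error")
    })
  }
  cn <- stage("simulate-cn", generate_cn_cohort(config))
  norm <- stage("build-norms", build_norm_table(cn, spec))
  ad <- stage("simulate-ad", generate_ad_cohort(config, norm))
  z <- stage("classify", classify_profiles(compute_z_profiles(ad, norm)))
  freq <- stage("frequencies", subtype_frequencies(z$subtype))
  subjects <- rbind(cn, ad)
  labelled <- merge(ad, z[, c("subject_id", "subtype")], by = "subject_id")
  labelled$true_subtype <- labelled$subtype
  long_subjects <- rbind(cn, labelled[names(cn)])
  long <- stage("simulate-longitudinal",
                generate_longitudinal(long_subjects, config))
  csf <- stage("simulate-csf", generate_csf(long_subjects, config))
  baseline <- stage("analyze-baseline",
                    table3_style_summary(ad, z, long))
  csf_summary <- stage("analyze-csf", csf_style_summary(csf))
  ad_long <- long[long$subtype != "CN", ]
  lmm <- stage("analyze-longitudinal", lapply(
    setNames(nm = config$longitudinal$measures),
    function(m) fit_lmm(ad_long, m)
  ))

  write_subjects(subjects, file.path(out_dir, "subjects.csv"))
  write_norm_table(norm, file.path(out_dir, "norm_table.csv"))
  write_subjects(z, file.path(out_dir, "labels.csv"))
  utils::write.csv(freq, file.path(out_dir, "subtype_frequencies.csv"),
                   row.names = FALSE)
  write_subjects(long, file.path(out_dir, "longitudinal.csv"))
  write_subjects(csf, file.path(out_dir, "csf.csv"))
  utils::write.csv(baseline, file.path(out_dir, "baseline_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(csf_summary, file.path(out_dir, "csf_summary.csv"),
                   row.names = FALSE)
  lmm_tab <- do.call(rbind, lapply(lmm, function(r) {
    data.frame(outcome = r$outcome, r$slopes,
               interaction_chisq = r$interaction$statistic,
               interaction_df = r$interaction$df,
               interaction_p = r$interaction$p_value,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(lmm_tab, file.path(out_dir, "lmm_slopes.csv"),
                   row.names = FALSE)
  log_lines <- c(
    sprintf("adsubtype %s", as.character(utils::packageVersion("adsubtype"))),
    sprintf("seed: %d", config$seed),
    sprintf("config digest: %s",
            paste(utils::head(unlist(config$subtype_mixture)), collapse = " ")),
    sprintf("n_cn: %d, n_ad: %d", nrow(cn), nrow(ad)),
    sprintf("norm cells: %d", nrow(norm)),
    sprintf("longitudinal rows: %d, csf rows: %d", nrow(long), nrow(csf)),
    sprintf("frequencies: %s",
            paste(sprintf("%s %.1f%%", freq$subtype, freq$pct),
                  collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(cn = cn, ad = ad, norm = norm, labels = z,
                 frequencies = freq, baseline = baseline, csf = csf,
                 csf_summary = csf_summary, lmm = lmm))
}
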