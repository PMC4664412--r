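#' Define age strata for normative tables
#'
#' Normative values of regional brain volumes change with age, so norms are
#' estimated within age strata. Adjacent strata may overlap so that a
#' cognitively normal subject contributes to every stratum whose interval
#' contains its age; overlapping stratification stabilises stratum means and
#' SDs near the bin edges. Bounds are inclusive.
#'
#' @param lower,upper numeric vectors of equal length: inclusive stratum
#'   bounds in years, ordered by `lower`.
#' @param genders character vector of gender levels; norms are built
#'   separately per gender.
#' @param min_stratum_n minimum number of normal subjects required in every
#'   (stratum, gender) cell before a norm table is accepted.
#' @return an object of class `strata_spec`.
#' @examples
#' default_strata()
#' strata_spec(c(55, 65, 70, 75), c(70, 80, 85, 90))
#' @export
strata_spec <- function(lower, upper, genders = GENDER_LEVELS,
                        min_stratum_n = 20) {
  if (length(lower) != length(upper) || length(lower) < 1) {
    stop_adsubtype("lower and upper must be non-empty vectors of equal length",
                   "adsubtype_config_error")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower)) {
    stop_adsubtype("each stratum needs finite bounds with upper > lower",
                   "adsubtype_config_error")
  }
  if (is.unsorted(lower, strictly = TRUE) || is.unsorted(upper)) {
    stop_adsubtype("strata must be ordered by increasing lower bound",
                   "adsubtype_config_error")
  }
  # joint coverage: no gap between consecutive strata
  if (length(lower) > 1 && any(lower[-1] > upper[-length(upper)])) {
    stop_adsubtype("strata must jointly cover the age range (no gaps)",
                   "adsubtype_config_error")
  }
  if (min_stratum_n < 2) {
    stop_adsubtype("min_stratum_n must be at least 2", "adsubtype_config_error")
  }
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         genders = genders, min_stratum_n = as.integer(min_stratum_n)),
    class = "strata_spec"
  )
}

#' Default age stratification: four overlapping strata covering 55-90
#'
#' 55-70, 65-80, 70-85, 75-90 years (inclusive), two gender levels.
#' @inheritParams strata_spec
#' @return a `strata_spec`.
#' @export
default_strata <- function(min_stratum_n = 20) {
  strata_spec(c(55, 65, 70, 75), c(70, 80, 85, 90),
              min_stratum_n = min_stratum_n)
}

#' @export
print.strata_spec <- function(x, ...) {
  cat(sprintf("Age strata (%d, inclusive bounds): %s\n", length(x$lower),
              paste(sprintf("[%g-%g]", x$lower, x$upper), collapse = " ")))
  cat(sprintf("Genders: %s; min n per cell: %d\n",
              paste(x$genders, collapse = "/"), x$min_stratum_n))
  invisible(x)
}

#' Assign an age to a single stratum for norm lookup
#'
#' Overlapping strata are fine for *building* norms, but a subject's Z-score
#' must be computed against exactly one cell. The lookup rule is
#' nearest-midpoint: the stratum whose midpoint is closest to the age, ties
#' resolved to the younger stratum. Over an age sweep the assigned index is
#' non-decreasing.
#'
#' @param age numeric vector of ages in years.
#' @param spec a [strata_spec()].
#' @param clamp if `TRUE`, ages outside the covered range are clamped to the
#'   nearest stratum with a warning instead of raising an error.
#' @return integer vector of stratum indices (1-based).
#' @export
assign_stratum <- function(age, spec, clamp = FALSE) {
  stopifnot(inherits(spec, "strata_spec"))
  if (any(!is.finite(age))) {
    stop_adsubtype("age must be finite", "adsubtype_validation_error")
  }
  lo <- min(spec$lower); hi <- max(spec$upper)
  out_of_range <- age < lo | age > hi
  if (any(out_of_range)) {
    if (!clamp) {
      stop_adsubtype(
        sprintf("age(s) outside normative range [%g, %g]: %s", lo, hi,
                paste(utils::head(age[out_of_range], 5), collapse = ", ")),
        "adsubtype_range_error"
      )
    }
    warning(sprintf("%d age(s) outside [%g, %g] clamped to nearest stratum",
                    sum(out_of_range), lo, hi))
  }
  mid <- (spec$lower + spec$upper) / 2
  # which.min returns the first (youngest) stratum on ties
  vapply(age, function(a) which.min(abs(a - mid)), integer(1))
}

#' Scale regional volumes by intracranial volume
#'
#' Head size varies substantially between individuals (and systematically
#' between genders), so raw ROI volumes are divided by intracranial volume
#' (ICV) to give dimensionless normalized volumes before any norm is applied.
#'
#' @param subjects data frame with columns `icv_mm3` and
#'   `hippocampal_mm3`, `frontal_mm3`, `temporal_mm3`, `parietal_mm3`.
#' @return data frame with columns `hippocampal`, `frontal`, `temporal`,
#'   `parietal` holding volume/ICV ratios.
#' @examples
#' normalize_volumes(data.frame(icv_mm3 = 1.5e6, hippocampal_mm3 = 4950,
#'   frontal_mm3 = 33000, temporal_mm3 = 17000, parietal_mm3 = 19000))
#' @export
normalize_volumes <- function(subjects) {
  needed <- c("icv_mm3", paste0(ROI_NAMES, "_mm3"))
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols) > 0) {
    stop_adsubtype(paste("missing column(s):",
                         paste(missing_cols, collapse = ", ")),
                   "adsubtype_validation_error")
  }
  icv <- subjects$icv_mm3
  if (any(!is.finite(icv)) || any(icv <= 0)) {
    stop_adsubtype("icv_mm3 must be finite and > 0",
                   "adsubtype_validation_error")
  }
  out <- lapply(ROI_NAMES, function(roi) {
    v <- subjects[[paste0(roi, "_mm3")]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop_adsubtype(sprintf("%s_mm3 must be finite and >= 0", roi),
                     "adsubtype_validation_error")
    }
    v / icv
  })
  names(out) <- ROI_NAMES
  as.data.frame(out)
}

#' Build an age- and gender-specific norm table from a CN cohort
#'
#' For every (stratum, gender, ROI) cell the sample mean and SD (n-1
#' denominator) of the normalized volumes of the cognitively normal subjects
#' whose age falls inside the stratum interval are recorded. With overlapping
#' strata a subject contributes to every stratum containing its age.
#'
#' @param cn_cohort data frame of CN subjects (see [read_subjects()] for the
#'   schema); all rows must have `diagnosis == "CN"`.
#' @param spec a [strata_spec()].
#' @return a data frame of class `norm_table` with columns `stratum`,
#'   `stratum_lower`, `stratum_upper`, `gender`, `roi`, `mean`, `sd`, `n`;
#'   the spec is attached as attribute `strata_spec`.
#' @export
build_norm_table <- function(cn_cohort, spec = default_strata()) {
  stopifnot(inherits(spec, "strata_spec"))
  if (!all(cn_cohort$diagnosis == "CN")) {
    stop_adsubtype("norm table must be built from CN subjects only",
                   "adsubtype_validation_error")
  }
  gender <- canonical_gender(cn_cohort$gender)
  ratios <- normalize_volumes(cn_cohort)
  rows <- list()
  insufficient <- character(0)
  degenerate <- character(0)
  for (s in seq_along(spec$lower)) {
    in_stratum <- cn_cohort$age >= spec$lower[s] & cn_cohort$age <= spec$upper[s]
    for (g in spec$genders) {
      idx <- which(in_stratum & gender == g)
      cell_id <- sprintf("stratum %d [%g-%g] %s", s, spec$lower[s],
                         spec$upper[s], g)
      if (length(idx) < spec$min_stratum_n) {
        insufficient <- c(insufficient,
                          sprintf("%s (n=%d)", cell_id, length(idx)))
        next
      }
      for (roi in ROI_NAMES) {
        x <- ratios[[roi]][idx]
        s_d <- stats::sd(x)
        if (s_d == 0) degenerate <- c(degenerate, paste(cell_id, roi))
        rows[[length(rows) + 1]] <- data.frame(
          stratum = s, stratum_lower = spec$lower[s],
          stratum_upper = spec$upper[s], gender = g, roi = roi,
          mean = mean(x), sd = s_d, n = length(idx),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(insufficient) > 0) {
    stop_adsubtype(
      paste0("insufficient CN subjects (min ", spec$min_stratum_n,
             ") in norm cell(s): ", paste(insufficient, collapse = "; ")),
      "adsubtype_insufficient_norm_error"
    )
  }
  if (length(degenerate) > 0) {
    stop_adsubtype(
      paste("zero variance in norm cell(s):",
            paste(degenerate, collapse = "; ")),
      "adsubtype_degenerate_norm_error"
    )
  }
  norm <- do.call(rbind, rows)
  attr(norm, "strata_spec") <- spec
  class(norm) <- c("norm_table", class(norm))
  norm
}

norm_cell <- function(norm, stratum, gender, roi) {
  hit <- norm$stratum == stratum & norm$gender == gender & norm$roi == roi
  if (sum(hit) != 1) {
    stop_adsubtype(
      sprintf("no norm cell for stratum %d, gender %s, roi %s",
              stratum, gender, roi),
      "adsubtype_lookup_error"
    )
  }
  norm[hit, ]
}

#' Compute Z-profiles against a norm table
#'
#' Each subject's four normalized ROI volumes are standardized against the
#' mean and SD of the matching (stratum, gender) norm cell:
#' `z = (volume/ICV - mean) / sd`. The stratum is the single one returned by
#' [assign_stratum()].
#'
#' @param subjects data frame of subjects to score.
#' @param norm a `norm_table` from [build_norm_table()].
#' @param spec the [strata_spec()]; defaults to the one attached to `norm`.
#' @param clamp passed to [assign_stratum()].
#' @return data frame with `subject_id`, `stratum`, `z_h`, `z_f`, `z_t`, `z_p`.
#' @export
compute_z_profiles <- function(subjects, norm,
                               spec = attr(norm, "strata_spec"),
                               clamp = FALSE) {
  stopifnot(inherits(norm, "norm_table"), inherits(spec, "strata_spec"))
  gender <- canonical_gender(subjects$gender)
  ratios <- normalize_volumes(subjects)
  stratum <- assign_stratum(subjects$age, spec, clamp = clamp)
  z <- matrix(NA_real_, nrow = nrow(subjects), ncol = length(ROI_NAMES),
              dimnames = list(NULL, ROI_NAMES))
  # vectorized per (stratum, gender) block
  for (s in unique(stratum)) {
    for (g in unique(gender)) {
      idx <- which(stratum == s & gender == g)
      if (length(idx) == 0) next
      for (roi in ROI_NAMES) {
        cell <- norm_cell(norm, s, g, roi)
        z[idx, roi] <- (ratios[[roi]][idx] - cell$mean) / cell$sd
      }
    }
  }
  data.frame(
    subject_id = if ("subject_id" %in% names(subjects)) subjects$subject_id
                 else seq_len(nrow(subjects)),
    stratum = stratum,
    z_h = z[, "hippocampal"], z_f = z[, "frontal"],
    z_t = z[, "temporal"], z_p = z[, "parietal"],
    stringsAsFactors = FALSE
  )
}

#' Write / read a norm table as CSV with a JSON sidecar
#'
#' The CSV holds one row per (stratum, gender, ROI) cell with means and SDs
#' printed at full double precision (17 significant digits), so a round trip
#' is lossless. The stratification spec travels in `<path>.json`.
#'
#' @param norm a `norm_table`.
#' @param path CSV file path.
#' @return `write_norm_table()` returns `path` invisibly; `read_norm_table()`
#'   returns the `norm_table`.
#' @export
write_norm_table <- function(norm, path) {
  stopifnot(inherits(norm, "norm_table"))
  out <- as.data.frame(norm)
  for (col in c("mean", "sd")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  spec <- attr(norm, "strata_spec")
  jsonlite::write_json(
    list(lower = spec$lower, upper = spec$upper, genders = spec$genders,
         min_stratum_n = spec$min_stratum_n, format_version = 1L),
    paste0(path, ".json"), digits = NA
  )
  invisible(path)
}

#' @rdname write_norm_table
#' @export
read_norm_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(mean = "numeric", sd = "numeric"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- strata_spec(side$lower, side$upper, genders = side$genders,
                      min_stratum_n = side$min_stratum_n)
  attr(tab, "strata_spec") <- spec
  class(tab) <- c("norm_table", class(tab))
  tab
}
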