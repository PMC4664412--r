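#' @keywords internal
"_PACKAGE"

# Canonical ROI order used throughout: bilateral sums of hippocampus,
# middle frontal, superior temporal and inferior parietal cortex.
ROI_NAMES <- c("hippocampal", "frontal", "temporal", "parietal")

# Subtype labels in the reporting order used by all frequency tables.
SUBTYPE_LEVELS <- c("BI", "HA", "CA", "BS")

GENDER_LEVELS <- c("female", "male")

#' Round half away from zero
#'
#' Percentages are reported rounded half-up (58.895 -> 58.9), not with
#' banker's rounding as [base::round()] would do.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_adsubtype <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "adsubtype_error")))
}

# Normalise free-form gender strings to the two canonical levels
# (case-insensitive, accepts M/F abbreviations).
canonical_gender <- function(gender) {
  g <- tolower(trimws(as.character(gender)))
  g[g %in% c("f", "female")] <- "female"
  g[g %in% c("m", "male")] <- "male"
  bad <- !g %in% GENDER_LEVELS & !is.na(g)
  if (any(bad)) {
    stop_adsubtype(
      sprintf("unrecognised gender value(s): %s",
              paste(unique(gender[bad]), collapse = ", ")),
      "adsubtype_validation_error"
    )
  }
  g
}
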