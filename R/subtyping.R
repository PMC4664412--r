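#' Classify atrophy subtype from a Z-profile
#'
#' Rule-based four-way classification of regional atrophy. A region shows
#' prominent atrophy when its Z-score falls strictly below the cutoff
#' (default -1.0). With H = hippocampal atrophy and C = atrophy in at least
#' one of the three cortical ROIs (frontal, temporal, parietal):
#'
#' * `BI` (both impaired): H and C
#' * `HA` (hippocampal atrophy only): H, not C
#' * `CA` (cortical atrophy only): C, not H
#' * `BS` (both spared): neither
#'
#' The four rules partition the Z-space: exactly one label fires for every
#' finite profile. A profile sitting exactly at the cutoff in all regions is
#' spared (the inequality is strict).
#'
#' @param z_h,z_f,z_t,z_p numeric vectors of hippocampal, frontal, temporal
#'   and parietal Z-scores (recycled to common length).
#' @param cutoff atrophy threshold on the Z scale (default -1.0).
#' @return factor with levels `BI`, `HA`, `CA`, `BS`.
#' @examples
#' classify_subtype(-2.20, -1.05, -1.38, -1.52)  # BI
#' classify_subtype(-1.0, -1.0, -1.0, -1.0)      # BS: boundary is spared
#' @export
classify_subtype <- function(z_h, z_f, z_t, z_p, cutoff = -1.0) {
  n <- max(length(z_h), length(z_f), length(z_t), length(z_p))
  z_h <- rep_len(z_h, n); z_f <- rep_len(z_f, n)
  z_t <- rep_len(z_t, n); z_p <- rep_len(z_p, n)
  if (!all(is.finite(c(z_h, z_f, z_t, z_p)))) {
    stop_adsubtype("all four Z-scores must be finite",
                   "adsubtype_validation_error")
  }
  if (!is.finite(cutoff)) {
    stop_adsubtype("cutoff must be finite", "adsubtype_config_error")
  }
  hip <- z_h < cutoff
  cort <- pmin(z_f, z_t, z_p) < cutoff  # "at least 1 of 3" == min below
  lab <- ifelse(hip, ifelse(cort, "BI", "HA"), ifelse(cort, "CA", "BS"))
  factor(lab, levels = SUBTYPE_LEVELS)
}

#' Classify a table of Z-profiles
#'
#' Convenience wrapper of [classify_subtype()] over the data frame returned
#' by [compute_z_profiles()]; appends a `subtype` column.
#'
#' @param zprofiles data frame with columns `z_h`, `z_f`, `z_t`, `z_p`.
#' @inheritParams classify_subtype
#' @return `zprofiles` with a `subtype` factor column added.
#' @export
classify_profiles <- function(zprofiles, cutoff = -1.0) {
  zprofiles$subtype <- classify_subtype(zprofiles$z_h, zprofiles$z_f,
                                        zprofiles$z_t, zprofiles$z_p,
                                        cutoff = cutoff)
  zprofiles
}

#' Subtype frequency table
#'
#' Counts and percentages (rounded half-up to one decimal) in the stable
#' label order BI, HA, CA, BS.
#'
#' @param labels vector of subtype labels (character or factor).
#' @return data frame with columns `subtype`, `n`, `pct` and attribute
#'   `total`.
#' @examples
#' subtype_frequencies(rep(c("BI", "HA", "CA", "BS"), c(96, 31, 19, 17)))
#' @export
subtype_frequencies <- function(labels) {
  if (length(labels) == 0) {
    stop_adsubtype("cannot tabulate an empty label list",
                   "adsubtype_empty_input_error")
  }
  labels <- as.character(labels)
  bad <- !labels %in% SUBTYPE_LEVELS
  if (any(bad)) {
    stop_adsubtype(paste("unknown subtype label(s):",
                         paste(unique(labels[bad]), collapse = ", ")),
                   "adsubtype_validation_error")
  }
  counts <- table(factor(labels, levels = SUBTYPE_LEVELS))
  total <- sum(counts)
  out <- data.frame(
    subtype = SUBTYPE_LEVELS,
    n = as.integer(counts),
    pct = round_half_up(100 * as.integer(counts) / total, 1),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  out
}
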