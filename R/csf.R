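# CSF biomarker analysis: amyloid-positivity cutoff, nonparametric group
# comparisons (Kruskal-Wallis, pairwise Mann-Whitney), median/IQR summaries.

#' Classify CSF amyloid positivity
#'
#' A subject is A-beta-positive when CSF A-beta 1-42 is at or below the
#' cutoff (boundary inclusive). The default 192 pg/mL is the established
#' xMAP/AlzBio3 threshold.
#'
#' @param abeta42 numeric vector of CSF A-beta 1-42 concentrations (pg/mL).
#' @param cutoff positivity threshold in pg/mL.
#' @return logical vector.
#' @examples
#' classify_abeta_positive(c(131, 216, 192))  # TRUE FALSE TRUE
#' @export
classify_abeta_positive <- function(abeta42, cutoff = 192) {
  if (any(is.na(abeta42)) || any(!is.finite(abeta42)) || any(abeta42 <= 0)) {
    stop_adsubtype("abeta42 must be finite, positive and non-missing",
                   "adsubtype_validation_error")
  }
  abeta42 <= cutoff
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square(k-1) p-value.
#'
#' @param groups list of numeric vectors, one per group.
#' @return an `adsubtype_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop_adsubtype("need >= 2 non-empty groups", "adsubtype_validation_error")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(x, g)
  new_test_result("Kruskal-Wallis", res$statistic, res$parameter, res$p.value)
}

# Exact two-sided Mann-Whitney p by enumeration of all choose(n1+n2, n1)
# assignments of the pooled (possibly tied, average-ranked) values to the
# first sample; two-sided p doubles the smaller tail of U around its mean.
mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # distance-from-center two-sided rule, robust under ties
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test (two-sided)
#'
#' Reports the U statistic of the first sample. The p-value is exact by
#' enumeration of all rank assignments when both samples have at most
#' `exact_max` observations (the enumeration handles ties via average
#' ranks); otherwise the tie-corrected normal approximation without
#' continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param exact_max maximum per-sample size for exact enumeration.
#' @return an `adsubtype_test` with `statistic` = U for `a`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, exact_max = 8) {
  if (length(a) == 0 || length(b) == 0) {
    stop_adsubtype("both samples must be non-empty",
                   "adsubtype_validation_error")
  }
  n1 <- length(a); n2 <- length(b)
  u <- sum(rank(c(a, b))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- mw_exact_p(a, b)
    method <- "Mann-Whitney U (exact)"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    )
    # fully tied data: rank variance is 0 and the z statistic is 0/0;
    # U sits at its null mean, so there is no evidence against the null
    if (!is.finite(p) && abs(u - n1 * n2 / 2) < 1e-9) p <- 1
    method <- "Mann-Whitney U (normal approximation)"
  }
  new_test_result(method, u, NA_real_, min(p, 1))
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param x non-empty numeric vector.
#' @return named numeric: `median`, `q25`, `q75`.
#' @export
median_iqr <- function(x) {
  if (length(x) == 0 || any(is.na(x))) {
    stop_adsubtype("sample must be non-empty with no missing values",
                   "adsubtype_validation_error")
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q25 = q[1], q75 = q[3])
}
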