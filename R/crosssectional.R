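# Baseline group comparisons: ANOVA with post-hoc pairs, ANCOVA with
# education as covariate, Pearson chi-square for categorical variables.

new_test_result <- function(test, statistic, df, p_value, post_hoc = NULL) {
  structure(
    list(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), post_hoc = post_hoc),
    class = "adsubtype_test"
  )
}

#' @export
print.adsubtype_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$post_hoc)) {
    cat("post-hoc pairs:\n")
    print(x$post_hoc, row.names = FALSE)
  }
  invisible(x)
}

check_groups <- function(outcome, group, min_per_group = 2) {
  keep <- is.finite(outcome) & !is.na(group)
  outcome <- outcome[keep]
  group <- factor(group[keep])
  group <- droplevels(group)
  if (nlevels(group) < 2) {
    stop_adsubtype("need at least 2 groups", "adsubtype_insufficient_data_error")
  }
  small <- table(group) < min_per_group
  if (any(small)) {
    stop_adsubtype(
      paste("group(s) with fewer than", min_per_group, "observations:",
            paste(names(which(small)), collapse = ", ")),
      "adsubtype_insufficient_data_error"
    )
  }
  list(outcome = outcome, group = group, n_dropped = sum(!keep))
}

#' One-way ANOVA with post-hoc pairwise comparisons
#'
#' F test of equal group means, with Tukey HSD (default) or
#' Bonferroni-adjusted pairwise t tests as the post-hoc procedure.
#' Missing values are dropped listwise.
#'
#' @param outcome numeric outcome vector.
#' @param group group label per observation.
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @return an `adsubtype_test` with statistic (F), df `(k-1, N-k)`,
#'   p-value, and a `post_hoc` data frame of pairwise adjusted p-values.
#' @export
one_way_anova <- function(outcome, group, posthoc = c("tukey", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  d <- check_groups(outcome, group)
  fit <- stats::aov(d$outcome ~ d$group)
  tab <- summary(fit)[[1]]
  ph <- if (posthoc == "tukey") {
    tk <- stats::TukeyHSD(fit)[[1]]
    pairs <- rownames(tk)
    data.frame(pair = pairs, diff = tk[, "diff"], p_adj = tk[, "p adj"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    pt <- stats::pairwise.t.test(d$outcome, d$group, p.adjust.method =
                                   "bonferroni")$p.value
    idx <- which(!is.na(pt), arr.ind = TRUE)
    data.frame(pair = paste(rownames(pt)[idx[, 1]], colnames(pt)[idx[, 2]],
                            sep = "-"),
               diff = NA_real_, p_adj = pt[idx], stringsAsFactors = FALSE)
  }
  new_test_result("one-way ANOVA", tab[1, "F value"],
                  c(tab[1, "Df"], tab[2, "Df"]), tab[1, "Pr(>F)"], ph)
}

#' ANCOVA: group effect adjusted for a covariate
#'
#' Fits `outcome ~ covariate + group` and reports the F test of the group
#' effect adjusted for the covariate (education years, in the baseline
#' neuropsychological comparisons). A constant covariate triggers a warning
#' and a fall back to plain ANOVA.
#'
#' @inheritParams one_way_anova
#' @param covariate numeric covariate vector.
#' @return an `adsubtype_test` for the adjusted group effect.
#' @export
ancova <- function(outcome, group, covariate) {
  keep <- is.finite(outcome) & !is.na(group) & is.finite(covariate)
  outcome <- outcome[keep]; group <- group[keep]; covariate <- covariate[keep]
  if (length(unique(covariate)) < 2) {
    warning("covariate is constant; falling back to one-way ANOVA")
    return(one_way_anova(outcome, group))
  }
  d <- check_groups(outcome, group)
  covariate <- covariate[] # already filtered jointly above
  fit <- stats::lm(outcome ~ covariate + factor(group))
  tab <- stats::anova(fit)
  grp_row <- "factor(group)"
  new_test_result("ANCOVA (group adjusted for covariate)",
                  tab[grp_row, "F value"],
                  c(tab[grp_row, "Df"], tab["Residuals", "Df"]),
                  tab[grp_row, "Pr(>F)"])
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction (the comparisons here are 2 x 4 tables of
#' gender and ApoE e4 carrier counts across subtypes; Yates' correction
#' applies only to 2 x 2 tables).
#'
#' @param tab matrix of non-negative integer counts.
#' @return an `adsubtype_test` with the X^2 statistic,
#'   df `(r-1)(k-1)` and upper-tail p-value.
#' @examples
#' # gender split across the four subtypes
#' chi_square_test(rbind(female = c(41, 21, 10, 7),
#'                       male = c(55, 10, 9, 10)))
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    stop_adsubtype("contingency table must hold non-negative integers",
                   "adsubtype_validation_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_adsubtype("contingency table has a zero row or column margin",
                   "adsubtype_validation_error")
  }
  res <- stats::chisq.test(tab, correct = FALSE)
  new_test_result("Pearson chi-square", res$statistic, res$parameter,
                  res$p.value)
}
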