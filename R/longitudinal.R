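# Linear mixed models for 2-year cognitive trajectories: random intercept
# per subject, fixed effects for subtype, time (years), their interaction
# and education; the subtype-by-time interaction carries the question of
# interest (do the subtypes progress at different rates?).

#' Fit the random-intercept trajectory model
#'
#' Fits, by REML via [lme4::lmer()],
#' `outcome ~ subtype * time + education + (1 | subject)`
#' with time in years so fixed-effect "slopes" are annual change. The joint
#' Wald chi-square test of the subtype-by-time interaction block tests
#' whether progression rates differ across subtypes. Per-subtype fitted
#' slopes are the time coefficient plus the matching interaction term;
#' the reference subtype's slope is the time coefficient itself.
#'
#' @param records long data frame with columns `subject_id`, `subtype`,
#'   `visit_time` (years), `education`, and the outcome column. Rows with a
#'   missing outcome are dropped; unbalanced panels are fine.
#' @param outcome name of the outcome column (e.g. `"mmse"`).
#' @param reference reference subtype level (default `"BI"`, the largest
#'   group).
#' @param include_education adjust for education (dropped automatically
#'   with a warning when the column is absent or constant).
#' @return an object of class `lmm_result`: fixed effects with SEs, variance
#'   components, the interaction Wald test, per-subtype slopes with SEs, the
#'   slope covariance matrix, and the `lmerMod` fit.
#' @export
fit_lmm <- function(records, outcome, reference = "BI",
                    include_education = TRUE) {
  for (col in c("subject_id", "subtype", "visit_time", outcome)) {
    if (!col %in% names(records)) {
      stop_adsubtype(paste("missing column:", col),
                     "adsubtype_validation_error")
    }
  }
  d <- records[is.finite(records[[outcome]]), , drop = FALSE]
  if (length(unique(d$visit_time)) < 2) {
    stop_adsubtype("need >= 2 distinct visit times to estimate slopes",
                   "adsubtype_rank_error")
  }
  subtypes <- unique(d$subtype)
  if (length(subtypes) < 2) {
    stop_adsubtype("need >= 2 subtypes", "adsubtype_validation_error")
  }
  singletons <- names(which(table(unique(d[c("subject_id", "subtype")])$subtype) < 2))
  if (length(singletons) > 0) {
    warning("subtype(s) with a single subject retained: ",
            paste(singletons, collapse = ", "))
  }
  lv <- c(reference, sort(setdiff(subtypes, reference)))
  d$subtype <- factor(d$subtype, levels = lv[lv %in% subtypes])
  d$y <- d[[outcome]]
  use_edu <- include_education && "education" %in% names(d) &&
    length(unique(d$education)) > 1
  if (include_education && !use_edu) {
    warning("education absent or constant; fitting without it")
  }
  form <- if (use_edu) {
    y ~ subtype * visit_time + education + (1 | subject_id)
  } else {
    y ~ subtype * visit_time + (1 | subject_id)
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  beta <- lme4::fixef(fit)
  # vcov can fail on fully degenerate (noiseless) fits; the point
  # estimates are still exact, with zero sampling variance
  V <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) {
    matrix(0, length(beta), length(beta),
           dimnames = list(names(beta), names(beta)))
  })
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_intercept <- vc$vcov[vc$grp == "subject_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]

  # joint Wald test of the interaction block
  int_idx <- grep(":visit_time$", names(beta))
  L <- beta[int_idx]
  W <- tryCatch(
    drop(t(L) %*% solve(V[int_idx, int_idx, drop = FALSE]) %*% L),
    error = function(e) NA_real_
  )
  int_df <- length(int_idx)
  int_p <- if (is.finite(W)) stats::pchisq(W, int_df, lower.tail = FALSE)
           else NA_real_

  # per-subtype slopes: contrast matrix rows = time + own interaction
  levels_fit <- levels(d$subtype)
  time_idx <- which(names(beta) == "visit_time")
  C <- matrix(0, nrow = length(levels_fit), ncol = length(beta),
              dimnames = list(levels_fit, names(beta)))
  C[, time_idx] <- 1
  for (s in levels_fit[-1]) {
    C[s, paste0("subtype", s, ":visit_time")] <- 1
  }
  slopes <- drop(C %*% beta)
  slope_vcov <- C %*% V %*% t(C)
  structure(
    list(outcome = outcome,
         fixed = data.frame(term = names(beta), estimate = unname(beta),
                            se = sqrt(diag(V)), stringsAsFactors = FALSE),
         var_intercept = var_intercept, var_resid = var_resid,
         interaction = list(statistic = W, df = int_df, p_value = int_p),
         slopes = data.frame(subtype = levels_fit, slope = unname(slopes),
                             se = sqrt(diag(slope_vcov)),
                             stringsAsFactors = FALSE),
         slope_vcov = slope_vcov,
         fit = fit),
    class = "lmm_result"
  )
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM for %s\n", x$outcome))
  cat(sprintf("  subtype x time Wald chi-sq = %.3f (df %d), p = %.4g\n",
              x$interaction$statistic, x$interaction$df,
              x$interaction$p_value))
  cat(sprintf("  variance: intercept %.4g, residual %.4g\n",
              x$var_intercept, x$var_resid))
  cat("  per-subtype annual slopes:\n")
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' Pairwise slope contrasts between subtypes
#'
#' All pairwise differences of the fitted per-subtype annual slopes, with
#' standard errors from the slope covariance matrix and two-sided Wald
#' (normal) p-values.
#'
#' @param result an `lmm_result` from [fit_lmm()].
#' @return data frame: `pair`, `difference`, `se`, `p_value`.
#' @export
slope_contrasts <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  s <- result$slopes
  V <- result$slope_vcov
  k <- nrow(s)
  if (k < 2) {
    stop_adsubtype("need >= 2 subtypes for contrasts",
                   "adsubtype_validation_error")
  }
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    pair = paste(s$subtype[pairs[1, ]], s$subtype[pairs[2, ]], sep = "-"),
    difference = s$slope[pairs[1, ]] - s$slope[pairs[2, ]],
    se = sqrt(V[cbind(pairs[1, ], pairs[1, ])] +
                V[cbind(pairs[2, ], pairs[2, ])] -
                2 * V[cbind(pairs[1, ], pairs[2, ])]),
    stringsAsFactors = FALSE
  )
  out$p_value <- ifelse(out$se > 0,
                        2 * stats::pnorm(-abs(out$difference / out$se)), 1)
  out
}
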