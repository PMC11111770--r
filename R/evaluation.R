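#' Clopper-Pearson exact binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` within `[0, 1]`.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Binary confusion table for a risk stratum
#'
#' Binarizes predictions and truth by [stratum_membership()] and counts
#' true/false positives/negatives.
#'
#' @param predicted,truth Character vectors of slide grades, equal
#'   length >= 1.
#' @param stratum One of [risk_strata()].
#' @return A `confusion_table`: list with `tp`, `fp`, `tn`, `fn`, `n`,
#'   `stratum`.
#' @export
confusion_for_stratum <- function(predicted, truth, stratum) {
  if (length(predicted) != length(truth) || length(truth) < 1) {
    stop("predicted and truth must be equal-length, nonempty")
  }
  p <- stratum_membership(predicted, stratum)
  t <- stratum_membership(truth, stratum)
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t),
                 n = length(t), stratum = stratum),
            class = "confusion_table")
}

#' Binary confusion table from logical calls
#'
#' @param calls,truth Logical vectors (positive = TRUE), equal length.
#' @param stratum Label recorded on the table.
#' @return A `confusion_table`.
#' @export
confusion_from_calls <- function(calls, truth, stratum = "ALL_ABNORMAL") {
  stopifnot(length(calls) == length(truth), length(truth) >= 1)
  structure(list(tp = sum(calls & truth), fp = sum(calls & !truth),
                 tn = sum(!calls & !truth), fn = sum(!calls & truth),
                 n = length(truth), stratum = stratum),
            class = "confusion_table")
}

.metric_with_ci <- function(num, den, conf) {
  if (den == 0) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  }
  ci <- clopper_pearson(num, den, conf)
  list(estimate = num / den, lower = unname(ci[1]), upper = unname(ci[2]))
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/n`, PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, each with a 95%
#' Clopper-Pearson interval. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param ct A `confusion_table`.
#' @param conf Confidence level (default 0.95).
#' @return A `diagnostic_report`: named list of metric lists
#'   (`estimate`, `lower`, `upper`) plus `n` and `stratum`.
#' @export
diagnostic_metrics <- function(ct, conf = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  structure(
    list(sensitivity = .metric_with_ci(ct$tp, ct$tp + ct$fn, conf),
         specificity = .metric_with_ci(ct$tn, ct$tn + ct$fp, conf),
         accuracy    = .metric_with_ci(ct$tp + ct$tn, ct$n, conf),
         ppv         = .metric_with_ci(ct$tp, ct$tp + ct$fp, conf),
         npv         = .metric_with_ci(ct$tn, ct$tn + ct$fn, conf),
         auc         = NULL,
         n = ct$n, stratum = ct$stratum),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> stratum %s, n = %d\n", x$stratum, x$n))
  for (nm in c("sensitivity", "specificity", "accuracy", "ppv", "npv",
               "auc")) {
    m <- x[[nm]]
    if (is.null(m)) next
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n", nm, m$estimate, m$lower,
                m$upper))
  }
  invisible(x)
}

#' Serialize a diagnostic report as JSON
#'
#' @param report A `diagnostic_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostic_report <- function(report, path) {
  stopifnot(inherits(report, "diagnostic_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Prevalence-weighted metric identities
#'
#' Links sensitivity, specificity and prevalence to the derived
#' population metrics:
#' `accuracy = prev * sens + (1 - prev) * spec`,
#' `npv = (1 - prev) spec / ((1 - prev) spec + prev (1 - sens))`,
#' `ppv = prev * sens / (prev * sens + (1 - prev)(1 - spec))`.
#'
#' @param sens,spec,prevalence Values in `[0, 1]`.
#' @return Named list `accuracy`, `npv`, `ppv` (`NaN` where the
#'   denominator is zero).
#' @export
prevalence_weighted_metrics <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1)
  acc <- prevalence * sens + (1 - prevalence) * spec
  npv_den <- (1 - prevalence) * spec + prevalence * (1 - sens)
  ppv_den <- prevalence * sens + (1 - prevalence) * (1 - spec)
  npv <- if (npv_den == 0) NaN else (1 - prevalence) * spec / npv_den
  if (prevalence == 0) npv <- 1
  ppv <- if (ppv_den == 0) NaN else prevalence * sens / ppv_den
  list(accuracy = acc, npv = npv, ppv = ppv)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction:
#' the probability a random positive outscores a random negative, ties
#' counting one half. The CI is a stratified bootstrap (resampling
#' positives and negatives separately), percentile method.
#'
#' @param scores Numeric vector of continuous (or binary) scores.
#' @param labels Logical (or 0/1) vector; both classes must be present.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `auc`, `lower`, `upper`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, conf = 0.95,
                    seed = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both positive and negative labels are required for an ROC")
  }
  auc_point <- function(s, l) {
    r <- rank(s) # midranks handle ties
    n_pos <- sum(l)
    n_neg <- sum(!l)
    (sum(r[l]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  auc <- auc_point(scores, labels)
  if (!is.null(seed)) set.seed(seed)
  pos <- which(labels)
  neg <- which(!labels)
  boots <- vapply(seq_len(n_boot), function(i) {
    # sample.int avoids base::sample's scalar-x pitfall for 1-element strata
    idx <- c(pos[sample.int(length(pos), length(pos), replace = TRUE)],
             neg[sample.int(length(neg), length(neg), replace = TRUE)])
    auc_point(scores[idx], labels[idx])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- quantile(boots, c(a, 1 - a), names = FALSE)
  list(auc = auc, lower = ci[1], upper = ci[2],
       n_pos = length(pos), n_neg = length(neg))
}

#' ROC curve coordinates
#'
#' @param scores,labels As in [roc_auc()].
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, one row
#'   per distinct score plus the endpoints, suitable for CSV export and
#'   plotting.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  out <- t(vapply(thr, function(t) {
    call <- scores >= t
    c(fpr = sum(call & !labels) / n_neg, tpr = sum(call & labels) / n_pos)
  }, numeric(2)))
  data.frame(threshold = thr, fpr = out[, "fpr"], tpr = out[, "tpr"])
}

#' Two-sided Pearson chi-squared comparison of two proportions
#'
#' Pearson chi-squared on the 2x2 success/failure table without
#' continuity correction; two-sided p-value from the chi-squared(1)
#' distribution.
#'
#' @param a_success,a_total,b_success,b_total Counts; totals > 0.
#' @return List with `chi2`, `p`, `significant` (p < 0.05).
#' @export
compare_proportions_chi2 <- function(a_success, a_total, b_success,
                                     b_total) {
  stopifnot(a_total > 0, b_total > 0,
            a_success >= 0, a_success <= a_total,
            b_success >= 0, b_success <= b_total)
  O <- rbind(c(a_success, a_total - a_success),
             c(b_success, b_total - b_success))
  if (any(colSums(O) == 0)) stop("degenerate table: an outcome margin is empty")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, significant = p < 0.05)
}

#' Sensitivity difference between two arms in percentage points
#'
#' `(sens_assisted - sens_unassisted) * 100`, rounded to one decimal,
#' as used to report the assisted-reading enhancement.
#'
#' @param assisted,unassisted `diagnostic_report`s, or bare
#'   sensitivities in `[0, 1]`.
#' @return Difference in percentage points (1 dp).
#' @export
sensitivity_difference <- function(assisted, unassisted) {
  get_sens <- function(x) {
    if (inherits(x, "diagnostic_report")) x$sensitivity$estimate else x
  }
  round((get_sens(assisted) - get_sens(unassisted)) * 100, 1)
}
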