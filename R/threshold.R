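#' ROC analysis of percentage test-method changes
#'
#' The reference method's percentage change labels each pair positive when it
#' exceeds `positive_pct` (strict inequality); the test method's percentage
#' change is the score. The AUC is the empirical (trapezoid / Mann-Whitney)
#' area with ties counted one half; the confidence interval and the p-value
#' against AUC = 0.5 use the DeLong variance by default, or a stratified
#' bootstrap.
#'
#' @param deltas a `delta_pairs` data.frame (see [compute_deltas()]).
#' @param positive_pct reference-change cutoff defining a true positive,
#'   percent (default 10).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level confidence level (default 0.95).
#' @param boot_n bootstrap replicates when `ci_method = "bootstrap"`.
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`, `p_value`,
#'   `curve` (data.frame threshold/sensitivity/specificity), `n_pos`,
#'   `n_neg`, plus the scores and labels for operating-point queries.
#' @examples
#' d <- data.frame(pct_ref = c(20, 15, 12, 5, -5, 2),
#'                 pct_test = c(18, 9, 14, 6, -2, -1))
#' roc_analysis(d)$auc
#' @export
roc_analysis <- function(deltas, positive_pct = 10,
                         ci_method = c("delong", "bootstrap"),
                         conf_level = 0.95, boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  labels <- deltas$pct_ref > positive_pct
  scores <- deltas$pct_test
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort_degenerate(sprintf(
      "roc_analysis: single-class input (%d positive, %d negative)",
      n_pos, n_neg
    ))
  }
  roc <- pROC::roc(
    response = labels, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )
  auc <- as.numeric(pROC::auc(roc))
  # pROC warns that CI/variance at AUC exactly 1 are degenerate; the values
  # (zero-width CI, zero variance) are still the correct empirical answer.
  ci <- if (ci_method == "delong") {
    suppressWarnings(pROC::ci.auc(roc, conf.level = conf_level,
                                  method = "delong"))
  } else {
    pROC::ci.auc(roc, conf.level = conf_level, method = "bootstrap",
                 boot.n = boot_n)
  }
  v <- suppressWarnings(pROC::var(roc, method = "delong"))
  z <- (auc - 0.5) / sqrt(v)
  crv <- pROC::coords(
    roc, "all", ret = c("threshold", "sensitivity", "specificity"),
    transpose = FALSE
  )
  names(crv) <- c("threshold", "sensitivity", "specificity")
  structure(
    list(
      auc = auc,
      ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
      ci_method = ci_method,
      p_value = 2 * pnorm(-abs(z)),
      curve = crv,
      n_pos = n_pos, n_neg = n_neg,
      scores = scores, labels = labels,
      positive_pct = positive_pct
    ),
    class = "roc_result"
  )
}

#' Sensitivity and specificity at a fixed change threshold
#'
#' Evaluates the decision rule "test-method percentage change greater than
#' `threshold`" (strict) against the labels stored in the ROC result.
#'
#' @param roc a `roc_result` from [roc_analysis()].
#' @param threshold percentage-change cutoff for the test method (default 8).
#' @return list with `sensitivity_pct`, `specificity_pct` and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
operating_point <- function(roc, threshold = 8) {
  stopifnot(inherits(roc, "roc_result"))
  pos_call <- roc$scores > threshold
  tp <- sum(pos_call & roc$labels)
  fp <- sum(pos_call & !roc$labels)
  fn <- sum(!pos_call & roc$labels)
  tn <- sum(!pos_call & !roc$labels)
  list(
    threshold = threshold,
    sensitivity_pct = 100 * tp / (tp + fn),
    specificity_pct = 100 * tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Youden-optimal threshold (convenience)
#'
#' Reported for reference only; the analysis fixes its operating point a
#' priori.
#'
#' @param roc a `roc_result`.
#' @return list with `threshold`, `sensitivity_pct`, `specificity_pct`.
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  i <- which.max(j)
  list(
    threshold = roc$curve$threshold[i],
    sensitivity_pct = 100 * roc$curve$sensitivity[i],
    specificity_pct = 100 * roc$curve$specificity[i]
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC for reference change > %g%%: AUC %.3f (%d%% CI %.3f-%.3f, %s), p = %.2g\n  %d positive / %d negative pairs\n",
    x$positive_pct, x$auc, 95, x$ci_low, x$ci_high, x$ci_method,
    x$p_value, x$n_pos, x$n_neg
  ))
  invisible(x)
}
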