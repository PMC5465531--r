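#' Paired cardiac-output measurements
#'
#' Builds the paired-measurement table consumed by the agreement statistics.
#'
#' @param patient_id vector of identifiers.
#' @param timepoint vector of ordinal timepoints.
#' @param co_ref reference-method CO (L/min), e.g. pulmonary artery catheter.
#' @param co_test test-method CO (L/min), e.g. transthoracic echo.
#' @return data.frame with one row per pair.
#' @export
paired_co <- function(patient_id, timepoint, co_ref, co_test) {
  n <- length(co_ref)
  if (length(patient_id) == 1L) patient_id <- rep(patient_id, n)
  if (length(timepoint) == 1L) timepoint <- rep(timepoint, n)
  if (length(co_test) != n || length(patient_id) != n || length(timepoint) != n) {
    abort_input("paired_co: all columns must have equal length")
  }
  if (any(!is.finite(co_ref)) || any(!is.finite(co_test)) ||
      any(co_ref <= 0) || any(co_test <= 0)) {
    abort_input("paired_co: CO values must be finite and > 0")
  }
  data.frame(
    patient_id = patient_id, timepoint = as.integer(timepoint),
    co_ref = as.numeric(co_ref), co_test = as.numeric(co_test)
  )
}

#' Pearson correlation between the two methods
#'
#' @param pairs data.frame with `co_ref` and `co_test` columns.
#' @return list with `r`, `p_value` and `n_pairs`.
#' @export
correlate <- function(pairs) {
  if (nrow(pairs) < 3L) {
    abort_input("correlate: at least 3 pairs required")
  }
  if (sd(pairs$co_ref) == 0 || sd(pairs$co_test) == 0) {
    abort_degenerate("correlate: a method has zero variance")
  }
  ct <- cor.test(pairs$co_ref, pairs$co_test, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(pairs))
}

#' Bland-Altman agreement analysis
#'
#' Differences are test minus reference. The bias line is the mean difference
#' by default; the limits of agreement are always bias +/- `loa_multiplier`
#' times the sample sd of the differences. `central_tendency = "median"`
#' moves only the bias line (some reports quote a median bias) while the
#' interval construction stays mean-based, the only construction consistent
#' with symmetric limits.
#'
#' @param pairs data.frame with `co_ref` and `co_test`.
#' @param central_tendency `"mean"` (default) or `"median"` for the bias line.
#' @param loa_multiplier multiplier on sd (default 1.96).
#' @return list of class `agreement_result`: `n_pairs`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, plus `r`/`p_value` slots left NA until
#'   [agreement_analysis()] fills them.
#' @export
bland_altman <- function(pairs, central_tendency = c("mean", "median"),
                         loa_multiplier = 1.96) {
  central_tendency <- match.arg(central_tendency)
  if (nrow(pairs) < 2L) {
    abort_input("bland_altman: at least 2 pairs required")
  }
  d <- pairs$co_test - pairs$co_ref
  bias <- if (central_tendency == "mean") mean(d) else median(d)
  sd_diff <- sd(d)
  structure(
    list(
      n_pairs = nrow(pairs),
      r = NA_real_, p_value = NA_real_,
      bias = bias, sd_diff = sd_diff,
      loa_low = bias - loa_multiplier * sd_diff,
      loa_high = bias + loa_multiplier * sd_diff,
      loa_multiplier = loa_multiplier,
      central_tendency = central_tendency,
      pe_pct = NA_real_
    ),
    class = "agreement_result"
  )
}

#' Critchley percentage error
#'
#' The half-width of the limits of agreement relative to the mean CO of the
#' population: `100 * multiplier * sd_diff / mean CO`, where the mean CO is
#' the grand mean of the pairwise means of the two methods (configurable to
#' the reference-method mean). Values at or below 30% are the conventional
#' interchangeability criterion.
#'
#' @param pairs the pairs the agreement was computed on.
#' @param agreement an `agreement_result` from [bland_altman()].
#' @param denominator `"pair_means"` (default) or `"reference"`.
#' @return percentage error (percent).
#' @export
percentage_error <- function(pairs, agreement,
                             denominator = c("pair_means", "reference")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(agreement, "agreement_result"))
  if (nrow(pairs) != agreement$n_pairs) {
    abort_input("percentage_error: pairs do not match the agreement result")
  }
  mu <- switch(denominator,
    pair_means = mean((pairs$co_ref + pairs$co_test) / 2),
    reference = mean(pairs$co_ref)
  )
  if (mu == 0) {
    abort_degenerate("percentage_error: zero mean CO")
  }
  100 * agreement$loa_multiplier * agreement$sd_diff / mu
}

#' Full agreement analysis: correlation, Bland-Altman, percentage error
#'
#' @inheritParams bland_altman
#' @inheritParams percentage_error
#' @return an `agreement_result` with `r`, `p_value` and `pe_pct` populated.
#' @examples
#' set.seed(1)
#' p <- paired_co(1:20, 1, rnorm(20, 6, 1.5) + 4, rnorm(20, 6, 1.5) + 4)
#' agreement_analysis(p)
#' @export
agreement_analysis <- function(pairs, central_tendency = "mean",
                               loa_multiplier = 1.96,
                               denominator = "pair_means") {
  res <- bland_altman(pairs, central_tendency, loa_multiplier)
  cc <- correlate(pairs)
  res$r <- cc$r
  res$p_value <- cc$p_value
  res$pe_pct <- percentage_error(pairs, res, denominator)
  res
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Agreement over %d pairs: r = %.3f (p = %.2g)\n  bias %.2f L/min (%s), LOA [%.2f, %.2f] L/min, PE %.1f%%\n",
    x$n_pairs, x$r, x$p_value, x$bias, x$central_tendency,
    x$loa_low, x$loa_high, x$pe_pct
  ))
  invisible(x)
}
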