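#' Analysis configuration
#'
#' All thresholds of the pipeline live here; none are hard-coded downstream.
#' The defaults are the shipped study profile: 15% four-quadrant exclusion
#' zone, 0.5 L/min polar exclusion zone, +/-30 degree polar concordance band,
#' reference change > 10% as the ROC positive rule, operating threshold of
#' 8% on the test method, 1.96 limits-of-agreement multiplier, precision
#' multiplier k = 2, mean-based bias, DeLong confidence intervals.
#'
#' @param fq_zone_pct four-quadrant exclusion-zone half-width (percent).
#' @param polar_zone_lmin polar exclusion radius (L/min).
#' @param polar_band_deg polar concordance band half-width (degrees).
#' @param roc_positive_pct reference-change cutoff for ROC positives (percent).
#' @param operating_threshold_pct operating threshold on the test-method
#'   change (percent).
#' @param loa_multiplier limits-of-agreement multiplier.
#' @param precision_k precision coverage multiplier (2 or 1.96).
#' @param central_tendency `"mean"` or `"median"` bias line.
#' @param ci_method `"delong"` or `"bootstrap"` AUC confidence interval.
#' @param pe_denominator `"pair_means"` or `"reference"`.
#' @param cv_pooling `"rms"` or `"mean"` pooling of per-subject CVs.
#' @param pi_literal use 3.14 instead of full-precision pi in the LVOT area.
#' @param seed RNG seed (used only by the bootstrap CI).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(fq_zone_pct = 15,
                            polar_zone_lmin = 0.5,
                            polar_band_deg = 30,
                            roc_positive_pct = 10,
                            operating_threshold_pct = 8,
                            loa_multiplier = 1.96,
                            precision_k = 2,
                            central_tendency = c("mean", "median"),
                            ci_method = c("delong", "bootstrap"),
                            pe_denominator = c("pair_means", "reference"),
                            cv_pooling = c("rms", "mean"),
                            pi_literal = FALSE,
                            seed = 1) {
  cfg <- list(
    fq_zone_pct = fq_zone_pct,
    polar_zone_lmin = polar_zone_lmin,
    polar_band_deg = polar_band_deg,
    roc_positive_pct = roc_positive_pct,
    operating_threshold_pct = operating_threshold_pct,
    loa_multiplier = loa_multiplier,
    precision_k = precision_k,
    central_tendency = match.arg(central_tendency),
    ci_method = match.arg(ci_method),
    pe_denominator = match.arg(pe_denominator),
    cv_pooling = match.arg(cv_pooling),
    pi_literal = isTRUE(pi_literal),
    seed = as.integer(seed)
  )
  numeric_fields <- c(
    "fq_zone_pct", "polar_zone_lmin", "polar_band_deg", "roc_positive_pct",
    "operating_threshold_pct", "loa_multiplier", "precision_k"
  )
  if (any(unlist(cfg[numeric_fields]) <= 0)) {
    abort_input("analysis_config: zones, thresholds and multipliers must be > 0")
  }
  class(cfg) <- "analysis_config"
  cfg
}

# Run a stage, translating a degeneracy into a named undefined-result entry
# instead of a crash.
.stage <- function(expr) {
  tryCatch(expr, hemotrend_degenerate_error = function(e) {
    list(undefined = TRUE, reason = conditionMessage(e))
  })
}

#' Run the full method-comparison analysis
#'
#' End-to-end pipeline: ingest a raw or derived measurements table, derive
#' per-pair CO values, compute replicate precision (raw input only),
#' agreement (correlation, Bland-Altman, percentage error) over all pairs,
#' paired 24-h changes for patients with two timepoints, four-quadrant and
#' polar trending, and ROC change detection with the configured operating
#' point. Deterministic given input and config (the seed is consumed only by
#' the bootstrap CI if selected). Statistical degeneracies (single-class ROC,
#' all-excluded trending, ...) appear as named undefined-result entries.
#'
#' @param input a CSV path, a data.frame in the raw or derived schema, or a
#'   `synthetic_cohort`.
#' @param config an [analysis_config()].
#' @return list of class `analysis_report` with elements `agreement`,
#'   `precision_ref`, `precision_test`, `trending`, `roc`,
#'   `operating_point`, `derived` (the per-pair table) and `provenance`.
#' @export
run_full_analysis <- function(input, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  source_label <- "in-memory"
  raw <- NULL
  if (inherits(input, "synthetic_cohort")) {
    raw <- input$raw
    source_label <- sprintf("synthetic cohort (seed %d)", input$params$seed)
  } else if (is.character(input) && length(input) == 1L) {
    source_label <- input
    df <- read_measurements(input)
    if (attr(df, "schema") == "raw") raw <- df else derived <- df
  } else if (is.data.frame(input)) {
    if (all(c("co_tte", "co_pac") %in% names(input))) {
      derived <- input
    } else {
      raw <- input
    }
  } else {
    abort_input("run_full_analysis: unsupported input type")
  }
  pi_const <- if (config$pi_literal) 3.14 else pi
  if (!is.null(raw)) {
    derived <- derive_co(raw, pi_const = pi_const)
  }
  if (!all(c("patient_id", "timepoint", "co_tte", "co_pac") %in% names(derived))) {
    abort_input("run_full_analysis: derived table lacks required columns")
  }

  pairs <- paired_co(derived$patient_id, derived$timepoint,
                     co_ref = derived$co_pac, co_test = derived$co_tte)
  agreement <- .stage(agreement_analysis(
    pairs,
    central_tendency = config$central_tendency,
    loa_multiplier = config$loa_multiplier,
    denominator = config$pe_denominator
  ))

  precision_ref <- precision_test <- list(undefined = TRUE,
                                          reason = "raw replicates not supplied")
  if (!is.null(raw)) {
    precision_ref <- .stage(precision_stats(
      replicate_sets(raw, "ref"), "reference (thermodilution)",
      precision_k = config$precision_k, pooling = config$cv_pooling
    ))
    precision_test <- .stage(precision_stats(
      replicate_sets(raw, "test"), "test (echo VTI)",
      precision_k = config$precision_k, pooling = config$cv_pooling
    ))
  }

  trending <- list(undefined = TRUE, reason = "fewer than 2 patients with two timepoints")
  roc <- trending
  op <- trending
  deltas <- NULL
  t1 <- pairs[pairs$timepoint == 1, ]
  t2 <- pairs[pairs$timepoint == 2, ]
  if (nrow(t2) >= 2) {
    # patients measured only once are not part of the change analysis
    deltas <- compute_deltas(t1[t1$patient_id %in% t2$patient_id, ], t2)
    trending <- .stage(trending_analysis(
      deltas,
      fq_zone_pct = config$fq_zone_pct,
      polar_zone_lmin = config$polar_zone_lmin,
      polar_band_deg = config$polar_band_deg,
      loa_multiplier = config$loa_multiplier
    ))
    if (config$ci_method == "bootstrap") set.seed(config$seed)
    roc <- .stage(roc_analysis(
      deltas,
      positive_pct = config$roc_positive_pct,
      ci_method = config$ci_method
    ))
    op <- if (inherits(roc, "roc_result")) {
      operating_point(roc, config$operating_threshold_pct)
    } else {
      list(undefined = TRUE, reason = "ROC undefined")
    }
  }

  structure(
    list(
      agreement = agreement,
      precision_ref = precision_ref,
      precision_test = precision_test,
      trending = trending,
      roc = roc,
      operating_point = op,
      derived = derived,
      deltas = deltas,
      provenance = list(
        config = unclass(config),
        input = source_label,
        n_rows = nrow(derived),
        package_version = as.character(utils::packageVersion("hemotrend"))
      )
    ),
    class = "analysis_report"
  )
}

#' Validate an analysis report
#'
#' Every numeric field must be finite or the containing stage must be an
#' explicit undefined-result entry; the provenance must echo a complete
#' configuration.
#'
#' @param report an `analysis_report`.
#' @return TRUE (invisibly), or an error describing the violation.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  check_stage <- function(x, name) {
    if (is.list(x) && isTRUE(x$undefined)) {
      if (is.null(x$reason)) stop(sprintf("%s: undefined without reason", name))
      return(invisible(NULL))
    }
    nums <- unlist(Filter(is.numeric, x))
    if (any(!is.finite(nums))) {
      stop(sprintf("%s: non-finite numeric field", name))
    }
  }
  check_stage(report$agreement, "agreement")
  check_stage(report$precision_ref, "precision_ref")
  check_stage(report$precision_test, "precision_test")
  check_stage(report$trending, "trending")
  check_stage(report$operating_point, "operating_point")
  if (inherits(report$roc, "roc_result")) {
    r <- report$roc
    stopifnot(is.finite(r$auc), r$auc >= 0, r$auc <= 1,
              r$ci_low <= r$auc, r$auc <= r$ci_high)
  }
  cfg <- report$provenance$config
  needed <- c(
    "fq_zone_pct", "polar_zone_lmin", "polar_band_deg", "roc_positive_pct",
    "operating_threshold_pct", "loa_multiplier", "precision_k",
    "central_tendency", "ci_method", "seed"
  )
  miss <- setdiff(needed, names(cfg))
  if (length(miss) > 0) {
    stop(sprintf("provenance config missing: %s", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Serialise a report to JSON
#'
#' Scores/labels and the per-pair tables are included so a saved report fully
#' determines the figures; re-running the same input and config reproduces
#' the JSON byte for byte.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  out <- unclass(report)
  for (nm in names(out)) {
    if (is.list(out[[nm]])) out[[nm]] <- unclass(out[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Cardiac-output method-comparison report\n")
  cat(sprintf("  input: %s (%d pairs)\n", x$provenance$input, x$provenance$n_rows))
  show <- function(stage, fmt, ...) {
    if (is.list(stage) && isTRUE(stage$undefined)) {
      cat(sprintf("  [undefined] %s\n", stage$reason))
    } else {
      cat(sprintf(fmt, ...))
    }
  }
  if (!isTRUE(x$agreement$undefined)) print(x$agreement)
  if (!isTRUE(x$precision_ref$undefined)) print(x$precision_ref)
  if (!isTRUE(x$precision_test$undefined)) print(x$precision_test)
  if (!isTRUE(x$trending$undefined)) print(x$trending)
  if (inherits(x$roc, "roc_result")) {
    print(x$roc)
    op <- x$operating_point
    cat(sprintf(
      "  at test change > %g%%: sensitivity %.0f%%, specificity %.0f%%\n",
      op$threshold, op$sensitivity_pct, op$specificity_pct
    ))
  }
  invisible(x)
}
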