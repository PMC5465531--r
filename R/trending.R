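#' Paired CO changes between two timepoints
#'
#' For every patient present at both timepoints, computes the absolute change
#' (second minus first) and the percentage change relative to that method's
#' own first measurement, for both methods.
#'
#' @param timepoint1_pairs,timepoint2_pairs data.frames as returned by
#'   [paired_co()], holding the first and second measurements.
#' @return data.frame of class `delta_pairs`: `patient_id`, `d_ref`, `d_test`
#'   (L/min) and `pct_ref`, `pct_test` (percent).
#' @export
compute_deltas <- function(timepoint1_pairs, timepoint2_pairs) {
  ids <- intersect(timepoint1_pairs$patient_id, timepoint2_pairs$patient_id)
  dropped <- setdiff(
    union(timepoint1_pairs$patient_id, timepoint2_pairs$patient_id), ids
  )
  if (length(dropped) > 0) {
    warning(sprintf(
      "compute_deltas: %d patient(s) without both timepoints skipped: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  if (length(ids) == 0) {
    abort_input("compute_deltas: no patients with both timepoints")
  }
  t1 <- timepoint1_pairs[match(ids, timepoint1_pairs$patient_id), ]
  t2 <- timepoint2_pairs[match(ids, timepoint2_pairs$patient_id), ]
  ok <- t1$co_ref > 0 & t1$co_test > 0
  if (any(!ok)) {
    warning("compute_deltas: patients with non-positive baseline excluded")
    t1 <- t1[ok, ]; t2 <- t2[ok, ]; ids <- ids[ok]
  }
  out <- data.frame(
    patient_id = ids,
    d_ref = t2$co_ref - t1$co_ref,
    d_test = t2$co_test - t1$co_test,
    pct_ref = 100 * (t2$co_ref - t1$co_ref) / t1$co_ref,
    pct_test = 100 * (t2$co_test - t1$co_test) / t1$co_test
  )
  class(out) <- c("delta_pairs", "data.frame")
  out
}

#' Four-quadrant concordance of paired percentage changes
#'
#' A pair is excluded when it falls inside the open central square, i.e. when
#' the percentage change is below the zone on BOTH axes. Concordance is the
#' percentage of included pairs whose changes agree in sign; more than 90%
#' is the conventional good-trending cutoff.
#'
#' @param deltas a `delta_pairs` data.frame (see [compute_deltas()]).
#' @param zone_pct half-width of the central exclusion square, percent
#'   (default 15).
#' @return list: `concordance_pct`, `n_included`, `n_excluded`, `n_total`,
#'   `good_trending` (concordance > 90).
#' @export
four_quadrant <- function(deltas, zone_pct = 15) {
  if (nrow(deltas) == 0) {
    abort_input("four_quadrant: empty delta set")
  }
  excluded <- abs(deltas$pct_ref) < zone_pct & abs(deltas$pct_test) < zone_pct
  inc <- deltas[!excluded, ]
  if (nrow(inc) == 0) {
    abort_degenerate("four_quadrant: all points inside the exclusion zone")
  }
  conc <- 100 * mean(sign(inc$pct_ref) == sign(inc$pct_test))
  list(
    concordance_pct = conc,
    n_included = nrow(inc),
    n_excluded = sum(excluded),
    n_total = nrow(deltas),
    good_trending = conc > 90
  )
}

#' Polar transform of one set of paired CO changes
#'
#' Each pair of absolute changes (reference, test) becomes a point on the
#' half-circle polar plot: the radius is the magnitude of the mean change
#' `(d_ref + d_test)/2`; the angle is the direction of the vector
#' `(d_ref, d_test)` measured from the line of identity (a 45-degree
#' rotation), with pairs whose mean change is negative folded by 180 degrees
#' into the half-circle so that concordant decreases land on the polar axis.
#'
#' @param deltas a `delta_pairs` data.frame.
#' @param zone_lmin exclusion radius in L/min; points with a mean change
#'   magnitude below it are flagged excluded (boundary included).
#' @return data.frame: `radius` (L/min), `angle_deg` in (-180, 180], and
#'   `included`.
#' @export
polar_transform <- function(deltas, zone_lmin = 0.5) {
  mean_change <- (deltas$d_ref + deltas$d_test) / 2
  theta <- atan2(deltas$d_test, deltas$d_ref) * 180 / pi - 45
  theta <- ifelse(mean_change < 0, theta + 180, theta)
  # wrap into (-180, 180]
  theta <- ((theta + 180) %% 360) - 180
  theta[theta == -180] <- 180
  data.frame(
    radius = abs(mean_change),
    angle_deg = theta,
    included = abs(mean_change) >= zone_lmin
  )
}

#' Polar-plot trending statistics
#'
#' Over the included points (radius at or above the exclusion zone), computes
#' the mean polar angle, the radial limits of agreement (mean +/- multiplier
#' times sd of the angles, or a percentile interval), and the polar
#' concordance (percentage of included angles within +/- the band). Good
#' trending is conventionally a mean angle within +/-5 degrees and radial LOA
#' within +/-30 degrees.
#'
#' @param polar data.frame from [polar_transform()].
#' @param concordance_band_deg half-width of the concordance band in degrees
#'   (default 30).
#' @param loa_multiplier multiplier on the angle sd (default 1.96).
#' @param loa_method `"parametric"` (default) or `"percentile"` (2.5/97.5).
#' @return list: `n_total`, `n_included`, `mean_angle_deg`, `sd_angle_deg`,
#'   `radial_loa_low_deg`, `radial_loa_high_deg`, `concordance_pct`.
#' @export
polar_stats <- function(polar, concordance_band_deg = 30,
                        loa_multiplier = 1.96,
                        loa_method = c("parametric", "percentile")) {
  loa_method <- match.arg(loa_method)
  inc <- polar[polar$included, ]
  if (nrow(inc) < 2L) {
    abort_degenerate(sprintf(
      "polar_stats: %d point(s) outside the exclusion zone; at least 2 required",
      nrow(inc)
    ))
  }
  m <- mean(inc$angle_deg)
  s <- sd(inc$angle_deg)
  if (loa_method == "parametric") {
    lo <- m - loa_multiplier * s
    hi <- m + loa_multiplier * s
  } else {
    q <- quantile(inc$angle_deg, c(0.025, 0.975), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  list(
    n_total = nrow(polar),
    n_included = nrow(inc),
    mean_angle_deg = m,
    sd_angle_deg = s,
    radial_loa_low_deg = lo,
    radial_loa_high_deg = hi,
    concordance_pct = 100 * mean(abs(inc$angle_deg) <= concordance_band_deg)
  )
}

#' Combined four-quadrant and polar trending analysis
#'
#' @param deltas a `delta_pairs` data.frame.
#' @param fq_zone_pct four-quadrant exclusion-zone half-width, percent.
#' @param polar_zone_lmin polar exclusion radius, L/min.
#' @param polar_band_deg polar concordance band, degrees.
#' @param loa_multiplier multiplier for the radial LOA.
#' @return list of class `trending_result` combining [four_quadrant()] and
#'   [polar_stats()] fields.
#' @export
trending_analysis <- function(deltas, fq_zone_pct = 15, polar_zone_lmin = 0.5,
                              polar_band_deg = 30, loa_multiplier = 1.96) {
  fq <- four_quadrant(deltas, fq_zone_pct)
  pol <- polar_stats(
    polar_transform(deltas, polar_zone_lmin),
    concordance_band_deg = polar_band_deg,
    loa_multiplier = loa_multiplier
  )
  structure(
    list(
      n_total = nrow(deltas),
      n_included_fq = fq$n_included,
      concordance_fq_pct = fq$concordance_pct,
      good_trending_fq = fq$good_trending,
      n_included_polar = pol$n_included,
      mean_polar_angle_deg = pol$mean_angle_deg,
      radial_loa_low_deg = pol$radial_loa_low_deg,
      radial_loa_high_deg = pol$radial_loa_high_deg,
      concordance_polar_pct = pol$concordance_pct
    ),
    class = "trending_result"
  )
}

#' @export
print.trending_result <- function(x, ...) {
  cat(sprintf(
    "Trending over %d change pairs:\n  four-quadrant concordance %.1f%% (%d included)\n  mean polar angle %.1f deg, radial LOA [%.1f, %.1f] deg, polar concordance %.1f%% (%d included)\n",
    x$n_total, x$concordance_fq_pct, x$n_included_fq,
    x$mean_polar_angle_deg, x$radial_loa_low_deg, x$radial_loa_high_deg,
    x$concordance_polar_pct, x$n_included_polar
  ))
  invisible(x)
}
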