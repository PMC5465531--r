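#' Bland-Altman plot
#'
#' Pair means against differences, with a solid bias line and dashed limits
#' of agreement.
#'
#' @param pairs data.frame with `co_ref` and `co_test`.
#' @param agreement an `agreement_result` computed on the same pairs.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(pairs, agreement) {
  df <- data.frame(
    m = (pairs$co_ref + pairs$co_test) / 2,
    d = pairs$co_test - pairs$co_ref
  )
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::geom_hline(yintercept = agreement$bias, linewidth = 0.6) +
    ggplot2::geom_hline(
      yintercept = c(agreement$loa_low, agreement$loa_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Mean CO of the two methods (L/min)",
      y = "Difference, test - reference (L/min)",
      title = sprintf(
        "Bland-Altman: bias %.2f, LOA [%.2f, %.2f] L/min",
        agreement$bias, agreement$loa_low, agreement$loa_high
      )
    ) +
    ggplot2::theme_bw()
}

#' Four-quadrant trending plot
#'
#' Percentage reference changes against percentage test changes with the
#' central exclusion square drawn.
#'
#' @param deltas a `delta_pairs` data.frame.
#' @param zone_pct exclusion-zone half-width (percent).
#' @return a ggplot object.
#' @export
plot_four_quadrant <- function(deltas, zone_pct = 15) {
  fq <- four_quadrant(deltas, zone_pct)
  lim <- max(abs(c(deltas$pct_ref, deltas$pct_test, zone_pct))) * 1.1
  ggplot2::ggplot(deltas, ggplot2::aes(x = pct_ref, y = pct_test)) +
    ggplot2::annotate("rect",
      xmin = -zone_pct, xmax = zone_pct, ymin = -zone_pct, ymax = zone_pct,
      fill = "grey85", colour = "grey40"
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::coord_fixed(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(
      x = "Reference change (%)", y = "Test change (%)",
      title = sprintf(
        "Four-quadrant plot: concordance %.0f%% (%d/%d included)",
        fq$concordance_pct, fq$n_included, fq$n_total
      )
    ) +
    ggplot2::theme_bw()
}

.half_circle <- function(r, n = 181) {
  th <- seq(-90, 90, length.out = n) * pi / 180
  data.frame(x = r * cos(th), y = r * sin(th))
}

#' Half-circle polar trending plot
#'
#' Points at (radius, polar angle) with the exclusion half-circle, the
#' +/- band axes (solid) and the radial limits of agreement (dotted).
#'
#' @param deltas a `delta_pairs` data.frame.
#' @param zone_lmin exclusion radius (L/min).
#' @param band_deg concordance band half-width (degrees).
#' @param loa_multiplier radial LOA multiplier.
#' @return a ggplot object.
#' @export
plot_polar <- function(deltas, zone_lmin = 0.5, band_deg = 30,
                       loa_multiplier = 1.96) {
  pol <- polar_transform(deltas, zone_lmin)
  st <- polar_stats(pol, concordance_band_deg = band_deg,
                    loa_multiplier = loa_multiplier)
  pts <- data.frame(
    x = pol$radius * cos(pol$angle_deg * pi / 180),
    y = pol$radius * sin(pol$angle_deg * pi / 180),
    included = pol$included
  )
  rmax <- max(pol$radius, zone_lmin) * 1.15
  ray <- function(a) data.frame(
    x = c(0, rmax * cos(a * pi / 180)), y = c(0, rmax * sin(a * pi / 180))
  )
  g <- ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_path(data = .half_circle(zone_lmin),
                       ggplot2::aes(x = x, y = y),
                       colour = "grey50") +
    ggplot2::geom_segment(x = 0, y = -rmax, xend = 0, yend = rmax,
                          colour = "grey70") +
    ggplot2::geom_segment(x = 0, y = 0, xend = rmax, yend = 0,
                          colour = "grey30")
  for (a in c(-band_deg, band_deg)) {
    g <- g + ggplot2::geom_path(data = ray(a),
                                ggplot2::aes(x = x, y = y),
                                linewidth = 0.5)
  }
  for (a in c(st$radial_loa_low_deg, st$radial_loa_high_deg)) {
    g <- g + ggplot2::geom_path(data = ray(a),
                                ggplot2::aes(x = x, y = y),
                                linetype = "dotted")
  }
  g +
    ggplot2::geom_point(ggplot2::aes(shape = included), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Mean CO change (L/min)", y = "",
      title = sprintf(
        "Polar plot: mean angle %.1f deg, radial LOA [%.1f, %.1f] deg",
        st$mean_angle_deg, st$radial_loa_low_deg, st$radial_loa_high_deg
      )
    ) +
    ggplot2::theme_bw()
}

#' ROC plot with the operating point marked
#'
#' @param roc a `roc_result`.
#' @param threshold operating threshold (percent) to mark.
#' @return a ggplot object.
#' @export
plot_roc <- function(roc, threshold = 8) {
  crv <- roc$curve[order(1 - roc$curve$specificity, roc$curve$sensitivity), ]
  op <- operating_point(roc, threshold)
  ggplot2::ggplot(crv, ggplot2::aes(x = 1 - specificity,
                                    y = sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::annotate("point",
      x = 1 - op$specificity_pct / 100, y = op$sensitivity_pct / 100,
      shape = 17, size = 3
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC: AUC %.2f (95%% CI %.2f-%.2f)",
                      roc$auc, roc$ci_low, roc$ci_high)
    ) +
    ggplot2::theme_bw()
}
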