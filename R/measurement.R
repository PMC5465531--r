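#' Cross-sectional area of the LVOT from repeated diameter measurements
#'
#' The left ventricular outflow tract is assumed circular; repeated diameter
#' measurements (nominally three) are averaged before squaring, i.e. the area
#' is \eqn{\pi (\bar d / 2)^2}.
#'
#' @param lvot_diameters numeric vector of LVOT diameters in cm (length >= 1).
#' @param pi_const value of pi to use. The default is full-precision `pi`;
#'   `3.14` reproduces the rounded constant used on some clinical worksheets.
#' @return LVOT area in cm^2.
#' @examples
#' lvot_area(c(1.8, 2.0, 2.2))
#' @export
lvot_area <- function(lvot_diameters, pi_const = pi) {
  if (length(lvot_diameters) == 0) {
    abort_input("lvot_area: empty diameter list")
  }
  if (!is.numeric(lvot_diameters) || any(!is.finite(lvot_diameters)) ||
      any(lvot_diameters <= 0)) {
    abort_input("lvot_area: all diameters must be finite and > 0")
  }
  if (length(lvot_diameters) != 3L) {
    message(sprintf(
      "lvot_area: %d diameter replicate(s) supplied (nominal is 3)",
      length(lvot_diameters)
    ))
  }
  pi_const * (mean(lvot_diameters) / 2)^2
}

#' One patient-timepoint of raw echocardiographic quantities
#'
#' @param patient_id identifier.
#' @param timepoint ordinal timepoint (1 or 2).
#' @param lvot_diameters LVOT diameters in cm, nominally 3.
#' @param vti_values velocity-time integrals in cm, nominally 5 consecutive
#'   cardiac cycles.
#' @param heart_rate heart rate in bpm during the VTI acquisition.
#' @return an object of class `echo_measurement`.
#' @export
echo_measurement <- function(patient_id, timepoint, lvot_diameters,
                             vti_values, heart_rate) {
  if (length(lvot_diameters) == 0 || length(vti_values) == 0) {
    abort_input("echo_measurement: diameters and VTIs must be non-empty")
  }
  if (any(lvot_diameters <= 0) || any(vti_values <= 0)) {
    abort_input("echo_measurement: diameters and VTIs must be > 0")
  }
  if (!is.numeric(heart_rate) || length(heart_rate) != 1L || heart_rate <= 0) {
    abort_input("echo_measurement: heart_rate must be a single value > 0")
  }
  if (length(vti_values) != 5L) {
    message(sprintf(
      "echo_measurement [%s/t%s]: %d VTI replicate(s) supplied (nominal is 5)",
      patient_id, timepoint, length(vti_values)
    ))
  }
  structure(
    list(
      patient_id = patient_id, timepoint = as.integer(timepoint),
      lvot_diameters = as.numeric(lvot_diameters),
      vti_values = as.numeric(vti_values),
      heart_rate = as.numeric(heart_rate)
    ),
    class = "echo_measurement"
  )
}

#' One patient-timepoint of repeated thermodilution boluses
#'
#' @param patient_id identifier.
#' @param timepoint ordinal timepoint.
#' @param bolus_co cardiac-output values in L/min from consecutive cold-saline
#'   boluses; nominally 5, at least 2 (replicate precision is undefined
#'   otherwise).
#' @return an object of class `thermodilution_series`.
#' @export
thermodilution_series <- function(patient_id, timepoint, bolus_co) {
  if (length(bolus_co) < 2L) {
    abort_input("thermodilution_series: at least 2 bolus values required")
  }
  if (any(!is.finite(bolus_co)) || any(bolus_co <= 0)) {
    abort_input("thermodilution_series: bolus values must be finite and > 0")
  }
  if (length(bolus_co) != 5L) {
    message(sprintf(
      "thermodilution_series [%s/t%s]: %d bolus value(s) supplied (nominal is 5)",
      patient_id, timepoint, length(bolus_co)
    ))
  }
  structure(
    list(
      patient_id = patient_id, timepoint = as.integer(timepoint),
      bolus_co = as.numeric(bolus_co)
    ),
    class = "thermodilution_series"
  )
}

#' Stroke volume and cardiac output from echo quantities
#'
#' Stroke volume is LVOT area times mean VTI (cm^3 = ml); cardiac output is
#' stroke volume times heart rate, converted to L/min.
#'
#' @param m an [echo_measurement()].
#' @param pi_const passed to [lvot_area()].
#' @return list with `sv_ml` (stroke volume, ml) and `co_lmin` (L/min).
#' @examples
#' m <- echo_measurement("p1", 1, c(2, 2, 2), rep(20, 5), 100)
#' echo_cardiac_output(m)
#' @export
echo_cardiac_output <- function(m, pi_const = pi) {
  stopifnot(inherits(m, "echo_measurement"))
  area <- lvot_area(m$lvot_diameters, pi_const = pi_const)
  sv_ml <- area * mean(m$vti_values)
  list(sv_ml = sv_ml, co_lmin = sv_ml * m$heart_rate / 1000)
}

#' Cardiac output from a thermodilution series
#'
#' The repeated bolus values are averaged.
#'
#' @param s a [thermodilution_series()].
#' @return cardiac output in L/min.
#' @export
pac_cardiac_output <- function(s) {
  stopifnot(inherits(s, "thermodilution_series"))
  mean(s$bolus_co)
}

#' Replicate-based precision and least significant change
#'
#' Each subject contributes one set of replicate measurements. The
#' within-subject coefficient of variation (CV) is sd/mean with the usual
#' n-1 denominator; CVs are pooled across subjects as a root mean square by
#' default (so the pooled CV^2 is the mean within-subject relative variance).
#' The precision of the averaged measurement is `100 * k * CV / sqrt(n)` with
#' n the common replicate count and k = 2 by default (1.96 is the usual
#' alternative), and the least significant change is precision times sqrt(2).
#'
#' @param replicate_sets list of numeric vectors, one per subject, each of
#'   length >= 2 and positive.
#' @param method_label label carried into the result.
#' @param precision_k coverage multiplier k (default 2).
#' @param pooling `"rms"` (default) or `"mean"` pooling of per-subject CVs.
#' @return list of class `precision_result` with `method_label`, `pooled_cv`,
#'   `n_replicates`, `precision_pct`, `lsc_pct`, and the per-subject CVs.
#' @examples
#' precision_stats(list(c(9, 10, 11)), "demo")
#' @export
precision_stats <- function(replicate_sets, method_label,
                            precision_k = 2,
                            pooling = c("rms", "mean")) {
  pooling <- match.arg(pooling)
  if (length(replicate_sets) == 0) {
    abort_input("precision_stats: no replicate sets supplied")
  }
  nm <- names(replicate_sets)
  if (is.null(nm)) nm <- as.character(seq_along(replicate_sets))
  lens <- lengths(replicate_sets)
  bad <- which(lens < 2L)
  if (length(bad) > 0) {
    abort_input(sprintf(
      "precision_stats: subject(s) %s have < 2 replicates",
      paste(nm[bad], collapse = ", ")
    ))
  }
  if (any(vapply(replicate_sets, function(x) any(x <= 0), logical(1)))) {
    abort_input("precision_stats: all replicates must be > 0")
  }
  cvs <- vapply(replicate_sets, function(x) sd(x) / mean(x), numeric(1))
  pooled_cv <- switch(pooling,
    rms = sqrt(mean(cvs^2)),
    mean = mean(cvs)
  )
  n_rep <- round(mean(lens))
  if (length(unique(lens)) > 1L) {
    message(sprintf(
      "precision_stats [%s]: unequal replicate counts (%s); using mean count %d",
      method_label, paste(sort(unique(lens)), collapse = "/"), n_rep
    ))
  }
  precision_pct <- 100 * precision_k * pooled_cv / sqrt(n_rep)
  structure(
    list(
      method_label = method_label,
      pooled_cv = pooled_cv,
      n_replicates = n_rep,
      n_subjects = length(replicate_sets),
      precision_pct = precision_pct,
      lsc_pct = precision_pct * sqrt(2),
      subject_cv = cvs
    ),
    class = "precision_result"
  )
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf(
    "Precision [%s]: pooled CV %.3f over %d subjects x %d replicates\n  precision %.2f%%, least significant change %.2f%%\n",
    x$method_label, x$pooled_cv, x$n_subjects, x$n_replicates,
    x$precision_pct, x$lsc_pct
  ))
  invisible(x)
}
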