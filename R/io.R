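#' Read a measurements CSV (raw or derived schema)
#'
#' Two schemas are accepted and auto-detected by column presence:
#'
#' * raw: `patient_id, timepoint, lvot_d1..lvot_d3, vti_1..vti_5,
#'   heart_rate, pac_co_1..pac_co_5` (missing cells allowed for absent
#'   replicates);
#' * derived: `patient_id, timepoint, co_tte, co_pac` (optionally `sv_tte`).
#'
#' A file matching both or neither schema is an error, not a guess.
#'
#' @param path CSV path (UTF-8, header required, decimal point).
#' @return data.frame with attribute `schema` set to `"raw"` or `"derived"`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("input file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  has_raw <- all(c("lvot_d1", "vti_1", "heart_rate", "pac_co_1") %in% names(df))
  has_derived <- all(c("co_tte", "co_pac") %in% names(df))
  if (has_raw && has_derived) {
    abort_input("input matches both the raw and derived schema; ambiguous")
  }
  if (!has_raw && !has_derived) {
    abort_input(paste0(
      "input matches neither schema; expected raw columns ",
      "(lvot_d1.., vti_1.., heart_rate, pac_co_1..) or derived (co_tte, co_pac)"
    ))
  }
  required <- c("patient_id", "timepoint")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort_input(sprintf("input missing column(s): %s", paste(miss, collapse = ", ")))
  }
  attr(df, "schema") <- if (has_raw) "raw" else "derived"
  df
}

#' Derive per-pair CO values from a raw measurements table
#'
#' Runs the measurement module row by row: echo CO from LVOT diameters, VTI
#' replicates and heart rate; reference CO as the mean of the thermodilution
#' boluses. Missing replicate cells are dropped before averaging.
#'
#' @param raw data.frame in the raw schema (see [read_measurements()]).
#' @param pi_const passed to [lvot_area()].
#' @return data.frame: `patient_id`, `timepoint`, `co_tte`, `co_pac`,
#'   `sv_tte`.
#' @export
derive_co <- function(raw, pi_const = pi) {
  d_cols <- grep("^lvot_d[0-9]+$", names(raw), value = TRUE)
  v_cols <- grep("^vti_[0-9]+$", names(raw), value = TRUE)
  p_cols <- grep("^pac_co_[0-9]+$", names(raw), value = TRUE)
  if (length(d_cols) == 0 || length(v_cols) == 0 || length(p_cols) == 0) {
    abort_input("derive_co: raw schema columns not found")
  }
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    diams <- as.numeric(row[d_cols]); diams <- diams[!is.na(diams)]
    vtis <- as.numeric(row[v_cols]); vtis <- vtis[!is.na(vtis)]
    boluses <- as.numeric(row[p_cols]); boluses <- boluses[!is.na(boluses)]
    m <- suppressMessages(
      echo_measurement(row$patient_id, row$timepoint, diams, vtis,
                       row$heart_rate)
    )
    s <- suppressMessages(
      thermodilution_series(row$patient_id, row$timepoint, boluses)
    )
    eco <- echo_cardiac_output(m, pi_const = pi_const)
    out[[i]] <- data.frame(
      patient_id = row$patient_id, timepoint = as.integer(row$timepoint),
      co_tte = eco$co_lmin, co_pac = pac_cardiac_output(s),
      sv_tte = eco$sv_ml
    )
  }
  do.call(rbind, out)
}

#' Replicate sets for precision analysis from a raw table
#'
#' @param raw data.frame in the raw schema.
#' @param method `"ref"` (thermodilution boluses) or `"test"` (VTI traces).
#' @return named list of per-row replicate vectors.
#' @export
replicate_sets <- function(raw, method = c("ref", "test")) {
  method <- match.arg(method)
  cols <- if (method == "ref") {
    grep("^pac_co_[0-9]+$", names(raw), value = TRUE)
  } else {
    grep("^vti_[0-9]+$", names(raw), value = TRUE)
  }
  sets <- lapply(seq_len(nrow(raw)), function(i) {
    x <- as.numeric(raw[i, cols])
    x[!is.na(x)]
  })
  names(sets) <- paste0(raw$patient_id, "/t", raw$timepoint)
  sets
}

#' Write the raw-measurements CSV for a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_raw_measurements <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write.csv(cohort$raw, path, row.names = FALSE)
  invisible(path)
}

#' Write a derived-CO CSV
#'
#' @param derived data.frame from [derive_co()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_derived_co <- function(derived, path) {
  write.csv(derived, path, row.names = FALSE)
  invisible(path)
}
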