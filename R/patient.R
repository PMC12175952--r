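# Per-patient daily device record container.

#' Per-patient daily device series
#'
#' Bundles one patient's daily remote-monitoring record (mean PAP, cardiac
#' output, blood pressures, night/day heart rate, activity minutes) with
#' the treatment metadata the analysis needs: drug start/stop dates, dose
#' history, the pre-drug baseline window and the catheterization wedge
#' pressure used for PVR imputation.
#'
#' @param patient_id identifier.
#' @param days data frame with a `day` column (Date or integer) plus any of
#'   `mpap`, `cardiac_output`, `sbp`, `dbp`, `night_hr`, `day_hr`,
#'   `activity_min`; rows strictly date-ordered, fields may be missing.
#' @param drug_start first dosing day.
#' @param drug_stop last dosing day (NA while on drug).
#' @param baseline_window length-2 vector of dates, the pre-drug window;
#'   must end on or before `drug_start`. Defaults to all pre-drug days, up
#'   to 90 days back.
#' @param dose_history data frame with columns `date`, `dose_mg`.
#' @param pawp_baseline catheter wedge pressure, mmHg, or NA.
#' @param instrumented logical; FALSE for snapshot-only patients.
#' @return object of class `patient_series`.
#' @export
patient_series <- function(patient_id, days, drug_start, drug_stop = NA,
                           baseline_window = NULL, dose_history = NULL,
                           pawp_baseline = NA, instrumented = TRUE) {
  if (!"day" %in% names(days)) stop("'days' needs a 'day' column")
  if (anyDuplicated(days$day))
    stop("duplicate days in series for patient ", patient_id)
  days <- days[order(days$day), , drop = FALSE]
  rownames(days) <- NULL
  with_vals <- function(col) col %in% names(days) && any(!is.na(days[[col]]))
  if (with_vals("mpap") && any(days$mpap <= 0, na.rm = TRUE))
    stop("pressures must be positive")
  if (with_vals("cardiac_output") &&
      any(days$cardiac_output <= 0, na.rm = TRUE))
    stop("cardiac output must be positive")
  if (with_vals("sbp") && with_vals("dbp") &&
      any(days$sbp < days$dbp, na.rm = TRUE))
    stop("sbp must be >= dbp")
  if (is.null(baseline_window)) {
    lo <- max(min(days$day), drug_start - 90)
    baseline_window <- c(lo, drug_start - 1)
  }
  if (baseline_window[2] > drug_start)
    stop("baseline window must end on or before drug start")
  if (!is.na(drug_stop) && drug_stop < drug_start)
    stop("drug stop before drug start for patient ", patient_id)
  structure(list(patient_id = patient_id, instrumented = instrumented,
                 drug_start = drug_start, drug_stop = drug_stop,
                 dose_history = dose_history,
                 baseline_window = baseline_window,
                 pawp_baseline = pawp_baseline, days = days),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("patient %s: %d device days (%s to %s)%s\n",
              x$patient_id, nrow(x$days),
              format(min(x$days$day)), format(max(x$days$day)),
              if (x$instrumented) "" else " [snapshot only]"))
  cat(sprintf("  drug start %s, stop %s; baseline %s to %s\n",
              format(x$drug_start), format(x$drug_stop),
              format(x$baseline_window[1]), format(x$baseline_window[2])))
  invisible(x)
}
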