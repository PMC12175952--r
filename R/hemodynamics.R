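# Remote-monitoring hemodynamics pipeline: derived resistances, rolling
# 3-day averages, baseline adjustment, cohort aggregation, stability and
# withdrawal-alert detection.
#
# All resistances are in Wood units (mmHg per L/min). Daily series are
# handled on a full calendar-day grid so that missing device days stay
# missing rather than silently shifting windows.

#' Total pulmonary resistance
#'
#' TPR = mean pulmonary artery pressure / cardiac output. Missing inputs
#' give a missing result (the day is excluded downstream).
#'
#' @param mpap mean pulmonary artery pressure, mmHg.
#' @param cardiac_output cardiac output, L/min; must be positive when present.
#' @return resistance in Wood units.
#' @export
compute_tpr <- function(mpap, cardiac_output) {
  if (any(cardiac_output <= 0, na.rm = TRUE))
    stop("cardiac output must be positive")
  mpap / cardiac_output
}

#' Total systemic resistance
#'
#' Mean arterial pressure is estimated as DBP + (SBP - DBP)/3; TSR =
#' MAP / cardiac output. A directly recorded MAP can be supplied instead
#' via `map`.
#'
#' @param sbp,dbp systolic and diastolic blood pressure, mmHg (sbp >= dbp).
#' @param cardiac_output cardiac output, L/min.
#' @param map optional directly measured mean arterial pressure; overrides
#'   the SBP/DBP estimate where non-missing.
#' @return resistance in Wood units.
#' @export
compute_tsr <- function(sbp, dbp, cardiac_output, map = NULL) {
  if (any(cardiac_output <= 0, na.rm = TRUE))
    stop("cardiac output must be positive")
  if (any(sbp < dbp, na.rm = TRUE))
    stop("systolic pressure must be >= diastolic pressure")
  m <- dbp + (sbp - dbp) / 3
  if (!is.null(map)) m <- ifelse(is.na(map), m, map)
  m / cardiac_output
}

#' Pulmonary vascular resistance with wedge-pressure imputation
#'
#' PVR = (mPAP - PAWP) / cardiac output. For device-monitored patients the
#' wedge pressure is not remeasured daily; the patient's baseline
#' right-heart-catheter value is imputed instead. Days on which
#' pawp >= mpap are flagged with a warning and returned missing.
#'
#' @param mpap mean pulmonary artery pressure, mmHg.
#' @param pawp (imputed) mean pulmonary arterial wedge pressure, mmHg.
#' @param cardiac_output cardiac output, L/min.
#' @return resistance in Wood units.
#' @export
compute_pvr <- function(mpap, pawp, cardiac_output) {
  if (any(cardiac_output <= 0, na.rm = TRUE))
    stop("cardiac output must be positive")
  bad <- !is.na(mpap) & !is.na(pawp) & pawp >= mpap
  if (any(bad))
    warning(sum(bad), " day(s) with pawp >= mpap set to missing")
  out <- (mpap - pawp) / cardiac_output
  out[bad] <- NA_real_
  out
}

#' Trailing 3-day average on a calendar grid
#'
#' For each calendar day, the mean of the value on that day and the previous
#' `width - 1` calendar days, requiring at least `min_present` non-missing
#' values; days failing the requirement are missing. Days absent from the
#' input count as missing, so device dropouts do not contract the window.
#'
#' @param day vector of dates (or integer day indices), strictly increasing.
#' @param value numeric values, may contain NA.
#' @param width window length in calendar days (default 3).
#' @param min_present minimum non-missing days per window (default 2).
#' @return data frame with columns `day` and `value` (the smoothed series)
#'   on the full calendar grid spanning the input.
#' @export
rolling_3day <- function(day, value, width = 3, min_present = 2) {
  if (length(day) != length(value)) stop("day and value lengths differ")
  if (length(day) == 0L)
    return(data.frame(day = day, value = numeric(0)))
  if (is.unsorted(as.numeric(day), strictly = TRUE))
    stop("days must be strictly increasing")
  grid <- seq(min(day), max(day), by = 1)
  v <- rep(NA_real_, length(grid))
  v[match(as.numeric(day), as.numeric(grid))] <- value
  out <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    w <- v[max(1L, i - width + 1L):i]
    if (sum(!is.na(w)) >= min_present) out[i] <- mean(w, na.rm = TRUE)
  }
  data.frame(day = grid, value = out)
}

# Internal: daily derived-variable series for one patient on the calendar
# grid of its device days.
.patient_variable <- function(patient, variable) {
  d <- patient$days
  v <- switch(variable,
    tpr = compute_tpr(d$mpap, d$cardiac_output),
    tsr = compute_tsr(d$sbp, d$dbp, d$cardiac_output),
    pvr = {
      pawp <- patient$pawp_baseline
      if (is.null(pawp) || is.na(pawp))
        stop("no baseline wedge pressure for patient ", patient$patient_id)
      compute_pvr(d$mpap, pawp, d$cardiac_output)
    },
    d[[variable]] %||% stop("unknown variable '", variable, "'"))
  list(day = d$day, value = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-adjusted, 3-day-averaged series for one patient
#'
#' Smooths the requested variable with [rolling_3day()], estimates the
#' patient's baseline as the mean of the smoothed values inside the
#' pre-drug baseline window (at least `min_baseline_days` non-missing
#' smoothed days required), and expresses every day as a difference from
#' baseline (`mode = "absolute"`) or a percent change (`mode = "percent"`).
#' Day indices are re-expressed relative to the drug start
#' (`align = "start"`, day 0 = first dosing day) or the drug stop
#' (`align = "stop"`) for withdrawal analyses.
#'
#' @param patient a `patient_series` object.
#' @param variable one of `"tpr"`, `"tsr"`, `"pvr"` or a raw column name
#'   (`"mpap"`, `"cardiac_output"`, `"night_hr"`, `"day_hr"`,
#'   `"activity_min"`, ...).
#' @param align `"start"` or `"stop"`.
#' @param mode `"absolute"` (value minus baseline) or `"percent"`
#'   (100 * (value/baseline - 1)).
#' @param min_baseline_days minimum non-missing smoothed baseline days.
#' @return data frame with columns `rel_day`, `value` (adjusted series) and
#'   attribute `baseline` (the baseline level).
#' @export
baseline_adjust <- function(patient, variable, align = c("start", "stop"),
                            mode = c("absolute", "percent"),
                            min_baseline_days = 3) {
  align <- match.arg(align)
  mode <- match.arg(mode)
  pv <- .patient_variable(patient, variable)
  sm <- rolling_3day(pv$day, pv$value)
  in_base <- sm$day >= patient$baseline_window[1] &
    sm$day <= patient$baseline_window[2]
  base_vals <- sm$value[in_base]
  if (sum(!is.na(base_vals)) < min_baseline_days)
    stop("insufficient baseline data for patient ", patient$patient_id,
         " (", sum(!is.na(base_vals)), " non-missing smoothed days)")
  base <- mean(base_vals, na.rm = TRUE)
  anchor <- if (align == "start") patient$drug_start else {
    if (is.null(patient$drug_stop) || is.na(patient$drug_stop))
      stop("patient ", patient$patient_id, " has no drug stop date")
    patient$drug_stop
  }
  adj <- if (mode == "absolute") sm$value - base else
    100 * (sm$value / base - 1)
  out <- data.frame(rel_day = as.integer(round(as.numeric(sm$day) -
                                                 as.numeric(anchor))),
                    value = adj)
  attr(out, "baseline") <- base
  out
}

#' Day-aligned cohort mean curve with 95% t-intervals
#'
#' Averages the baseline-adjusted, 3-day-averaged series across patients at
#' each relative day and attaches a two-sided t-interval (df = n - 1). Days
#' contributed by fewer than `min_patients` patients are omitted; patients
#' with insufficient baseline data are excluded with a message.
#'
#' @param patients list of `patient_series`.
#' @param variable,align,mode passed to [baseline_adjust()].
#' @param conf confidence level (default 0.95).
#' @param min_patients minimum contributing patients per emitted day.
#' @param rel_day_range optional integer range `c(lo, hi)` restricting the
#'   emitted relative days.
#' @return data frame with columns `rel_day`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
cohort_curve <- function(patients, variable, align = c("start", "stop"),
                         mode = c("absolute", "percent"), conf = 0.95,
                         min_patients = 2, rel_day_range = NULL) {
  align <- match.arg(align)
  mode <- match.arg(mode)
  series <- list()
  for (p in patients) {
    s <- tryCatch(baseline_adjust(p, variable, align = align, mode = mode),
                  error = function(e) {
                    message("excluding patient ", p$patient_id, ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(s)) series[[length(series) + 1L]] <- s
  }
  if (!length(series)) stop("no patients with usable baseline data")
  all <- do.call(rbind, series)
  all <- all[!is.na(all$value), , drop = FALSE]
  if (!is.null(rel_day_range))
    all <- all[all$rel_day >= rel_day_range[1] &
                 all$rel_day <= rel_day_range[2], , drop = FALSE]
  days <- sort(unique(all$rel_day))
  rows <- lapply(days, function(d) {
    x <- all$value[all$rel_day == d]
    n <- length(x)
    if (n < min_patients) return(NULL)
    m <- mean(x)
    half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) *
      stats::sd(x) / sqrt(n) else 0
    data.frame(rel_day = d, mean = m, ci_lo = m - half, ci_hi = m + half,
               n = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no day reached the minimum patient count")
  rownames(out) <- NULL
  out
}

#' Time to hemodynamic stability of a smoothed TPR series
#'
#' Daily change is the absolute difference between consecutive calendar
#' days of the 3-day-averaged series. The stability event occurs on the
#' last day of the first window of `w` consecutive daily changes in which
#' at least `k` changes are below `delta` Wood units; changes that cannot
#' be formed because of missing days count as non-qualifying. Series too
#' short to contain a full window are censored at the series end.
#'
#' @param day dates or integer day indices, strictly increasing.
#' @param value smoothed (3-day average) TPR values.
#' @param delta change threshold in Wood units (default 0.15).
#' @param k required sub-threshold changes per window (default 6).
#' @param w window length in days (default 7).
#' @return list with `time` (day value of the event, or of the last day if
#'   censored) and `event` (logical).
#' @export
stability_time <- function(day, value, delta = 0.15, k = 6, w = 7) {
  if (delta <= 0) stop("delta must be positive")
  if (k > w) stop("k cannot exceed the window length w")
  if (length(day) != length(value)) stop("day and value lengths differ")
  if (length(day) == 0L) return(list(time = NA, event = FALSE))
  if (is.unsorted(as.numeric(day), strictly = TRUE))
    stop("days must be strictly increasing")
  grid <- seq(min(day), max(day), by = 1)
  v <- rep(NA_real_, length(grid))
  v[match(as.numeric(day), as.numeric(grid))] <- value
  if (length(grid) < w + 1L)
    return(list(time = grid[length(grid)], event = FALSE))
  chg <- abs(diff(v))                      # change ending on grid[i + 1]
  ok <- !is.na(chg) & chg < delta
  for (t in seq.int(w, length(chg))) {
    if (sum(ok[(t - w + 1L):t]) >= k)
      return(list(time = grid[t + 1L], event = TRUE))
  }
  list(time = grid[length(grid)], event = FALSE)
}

#' Per-patient time to TPR stability after drug start or withdrawal
#'
#' Applies [stability_time()] to the patient's 3-day-averaged TPR,
#' restricted to days from drug start (`phase = "onset"`) or from drug stop
#' (`phase = "withdrawal"`), and reports the event day relative to that
#' anchor.
#'
#' @param patient a `patient_series`.
#' @param phase `"onset"` or `"withdrawal"`.
#' @param delta,k,w passed to [stability_time()].
#' @return list with `time` (days since the anchor), `event` (logical).
#' @export
patient_stability <- function(patient, phase = c("onset", "withdrawal"),
                              delta = 0.15, k = 6, w = 7) {
  phase <- match.arg(phase)
  anchor <- if (phase == "onset") patient$drug_start else {
    if (is.null(patient$drug_stop) || is.na(patient$drug_stop))
      stop("patient ", patient$patient_id, " has no drug stop date")
    patient$drug_stop
  }
  pv <- .patient_variable(patient, "tpr")
  sm <- rolling_3day(pv$day, pv$value)
  sm <- sm[sm$day >= anchor, , drop = FALSE]
  if (phase == "onset" && !is.null(patient$drug_stop) &&
      !is.na(patient$drug_stop))
    sm <- sm[sm$day <= patient$drug_stop, , drop = FALSE]
  st <- stability_time(sm$day, sm$value, delta = delta, k = k, w = w)
  list(time = as.numeric(st$time) - as.numeric(anchor), event = st$event)
}

#' Kaplan-Meier median time with 95% confidence interval
#'
#' Product-limit estimate of the time-to-stability distribution; the median
#' is the first time at which survival drops to 0.5 or below, with a
#' log-log transformed confidence interval. With no events the median is
#' undefined and flagged as censored.
#'
#' @param times positive event/censoring times.
#' @param events logical (or 0/1) event indicators.
#' @param conf confidence level.
#' @return list with `median`, `ci_lo`, `ci_hi`, `n`, `n_events`,
#'   `all_censored`, and the underlying `survival::survfit` object as `fit`.
#' @export
km_summary <- function(times, events, conf = 0.95) {
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (any(times <= 0)) stop("times must be positive")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  list(median = med,
       ci_lo = unname(tab[grep("LCL", names(tab))]),
       ci_hi = unname(tab[grep("UCL", names(tab))]),
       n = length(times), n_events = sum(events),
       all_censored = sum(events) == 0L,
       fit = fit)
}

#' First post-withdrawal mean-PAP alert day
#'
#' Baseline mPAP is the mean of the 3-day-averaged mPAP inside the
#' patient's baseline window; the alert fires on the first day after drug
#' stop whose 3-day-average mPAP is at least baseline * (1 + threshold) —
#' the accelerated-clinical-visit trigger of remote follow-up.
#'
#' @param patient a `patient_series` with a drug stop date.
#' @param threshold fractional increase over baseline (default 0.10).
#' @return list with `day` (date of first alert, or NA if none),
#'   `baseline`, `alert_level`.
#' @export
withdrawal_alert <- function(patient, threshold = 0.10) {
  pv <- .patient_variable(patient, "mpap")
  sm <- rolling_3day(pv$day, pv$value)
  in_base <- sm$day >= patient$baseline_window[1] &
    sm$day <= patient$baseline_window[2]
  base <- mean(sm$value[in_base], na.rm = TRUE)
  if (!is.finite(base)) stop("baseline mPAP not computable for patient ",
                             patient$patient_id)
  if (is.null(patient$drug_stop) || is.na(patient$drug_stop))
    stop("patient ", patient$patient_id, " has no drug stop date")
  level <- base * (1 + threshold)
  post <- sm[sm$day > patient$drug_stop & !is.na(sm$value), , drop = FALSE]
  if (!nrow(post)) return(list(day = NA, baseline = base,
                               alert_level = level))
  # small relative tolerance so threshold arithmetic is not defeated by
  # floating-point representation of the level
  hit <- which(post$value >= level * (1 - 1e-12))
  list(day = if (length(hit)) post$day[hit[1]] else NA,
       baseline = base, alert_level = level)
}

#' Paired change between baseline and follow-up
#'
#' Paired Student's t test (`"paired-t"`: mean difference with t-interval),
#' Wilcoxon signed-rank (`"wilcoxon"`: Hodges-Lehmann shift), or paired t
#' on the natural-log scale back-transformed to a geometric mean ratio
#' (`"log-paired-t"`, as used for NT-proBNP).
#'
#' @param baseline,follow_up paired measurement vectors (equal length,
#'   at least 2 complete pairs).
#' @param method one of `"paired-t"`, `"wilcoxon"`, `"log-paired-t"`.
#' @param variable optional label carried into the result.
#' @param conf confidence level.
#' @return object of class `endpoint_change`: list with `variable`,
#'   `method`, `baseline`, `follow_up` (the two means, geometric for the
#'   log method), `change` (difference, HL shift, or geometric mean ratio),
#'   `ci_lo`, `ci_hi`, `p_value`, `n`, `degenerate` (TRUE when the paired
#'   differences have zero variance and the p value is undefined).
#' @export
endpoint_change <- function(baseline, follow_up,
                            method = c("paired-t", "wilcoxon",
                                       "log-paired-t"),
                            variable = "", conf = 0.95) {
  method <- match.arg(method)
  if (length(baseline) != length(follow_up))
    stop("baseline and follow-up must be paired (equal length)")
  keep <- !is.na(baseline) & !is.na(follow_up)
  b <- baseline[keep]; f <- follow_up[keep]
  if (length(b) < 2) stop("need at least 2 complete pairs")
  out <- list(variable = variable, method = method, n = length(b),
              degenerate = FALSE)
  if (method == "paired-t") {
    out$baseline <- mean(b); out$follow_up <- mean(f)
    d <- f - b
    out$change <- mean(d)
    if (.zero_var(d)) {
      out$degenerate <- TRUE
      out$ci_lo <- out$ci_hi <- out$change
      out$p_value <- NA_real_
    } else {
      tt <- stats::t.test(f, b, paired = TRUE, conf.level = conf)
      out$ci_lo <- tt$conf.int[1]; out$ci_hi <- tt$conf.int[2]
      out$p_value <- tt$p.value
    }
  } else if (method == "wilcoxon") {
    out$baseline <- stats::median(b); out$follow_up <- stats::median(f)
    d <- f - b
    if (all(d == 0)) {
      out$degenerate <- TRUE
      out$change <- 0; out$ci_lo <- out$ci_hi <- 0
      out$p_value <- NA_real_
    } else {
      wt <- suppressWarnings(stats::wilcox.test(f, b, paired = TRUE,
                                                conf.int = TRUE,
                                                conf.level = conf))
      out$change <- unname(wt$estimate)
      out$ci_lo <- wt$conf.int[1]; out$ci_hi <- wt$conf.int[2]
      out$p_value <- wt$p.value
    }
  } else {                                  # log-paired-t
    if (any(b <= 0) || any(f <= 0))
      stop("log-scale analysis requires positive values")
    lb <- log(b); lf <- log(f)
    out$baseline <- exp(mean(lb)); out$follow_up <- exp(mean(lf))
    d <- lf - lb
    out$change <- exp(mean(d))              # geometric mean ratio
    if (.zero_var(d)) {
      out$degenerate <- TRUE
      out$ci_lo <- out$ci_hi <- out$change
      out$p_value <- NA_real_
    } else {
      tt <- stats::t.test(lf, lb, paired = TRUE, conf.level = conf)
      out$ci_lo <- exp(tt$conf.int[1]); out$ci_hi <- exp(tt$conf.int[2])
      out$p_value <- tt$p.value
    }
  }
  class(out) <- "endpoint_change"
  out
}

#' @export
print.endpoint_change <- function(x, ...) {
  lab <- if (nzchar(x$variable)) paste0(x$variable, ": ") else ""
  cat(sprintf("%s%s, n = %d\n", lab, x$method, x$n))
  cat(sprintf("  baseline %.3g -> follow-up %.3g; change %.3g (%.3g to %.3g), p = %s\n",
              x$baseline, x$follow_up, x$change, x$ci_lo, x$ci_hi,
              if (is.na(x$p_value)) "NA (degenerate)" else
                format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Exposure-response table and rank correlation
#'
#' Joins per-patient steady-state drug exposure (AUC) with the percent TPR
#' change, grouped by assigned dose, and computes the Spearman rank
#' correlation of exposure against percent change (negative when higher
#' exposure gives a larger TPR reduction). With fewer than 3 joined
#' patients, or a constant response, the correlation is suppressed (NA)
#' with a note.
#'
#' @param dose_mg named vector (by patient id) of assigned doses.
#' @param auc named vector of steady-state AUC, ug.h/L.
#' @param delta_tpr_pct named vector of percent TPR change from baseline.
#' @return list with `table` (patient_id, dose_mg, auc, delta_tpr_pct),
#'   `rho`, `p_value`, `n`, `note`.
#' @export
exposure_response <- function(dose_mg, auc, delta_tpr_pct) {
  ids <- intersect(names(auc), names(delta_tpr_pct))
  tab <- data.frame(patient_id = ids,
                    dose_mg = unname(dose_mg[ids]),
                    auc = unname(auc[ids]),
                    delta_tpr_pct = unname(delta_tpr_pct[ids]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$dose_mg, tab$auc), , drop = FALSE]
  rownames(tab) <- NULL
  out <- list(table = tab, rho = NA_real_, p_value = NA_real_,
              n = nrow(tab), note = "")
  if (nrow(tab) < 3) {
    out$note <- "fewer than 3 joined patients; correlation suppressed"
  } else if (stats::sd(tab$delta_tpr_pct) == 0 || stats::sd(tab$auc) == 0) {
    out$note <- "constant exposure or response; correlation undefined"
  } else {
    ct <- suppressWarnings(stats::cor.test(tab$auc, tab$delta_tpr_pct,
                                           method = "spearman"))
    out$rho <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  out
}

# Differences whose variance is zero up to floating-point noise make the
# paired t statistic undefined.
.zero_var <- function(d) stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))
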