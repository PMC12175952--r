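# Delimited-table readers/writers and the end-to-end analysis driver.
#
# Formats: comma-separated, single header row, ISO-8601 dates, missing
# values as empty fields. Relative day indexing is 0-based with day 0 the
# event day (drug start or stop).

#' Read per-patient dose/DLT observations
#'
#' Expects columns `patient_id`, `dose_mg`, `dlt` (0/1) and
#' `enrolment_order`; header or value violations are reported with row
#' numbers. A header-only file yields an empty observation set with a
#' warning.
#'
#' @param path CSV file path.
#' @param model optional `crm_model` used to map `dose_mg` to dose indices
#'   (unknown doses are an error).
#' @return a `tox_obs` data frame in enrolment order, with a `dose_mg`
#'   column and, when `model` is given, validated `dose_index`.
#' @export
read_observations <- function(path, model = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "dose_mg", "dlt", "enrolment_order")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("no observation rows in ", path)
    out <- tox_obs(integer(0), integer(0))
    out$dose_mg <- numeric(0)
    return(out)
  }
  bad <- which(!df$dlt %in% c(0, 1))
  if (length(bad))
    stop("non-binary dlt in row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  df <- df[order(df$enrolment_order), , drop = FALSE]
  if (!is.null(model)) {
    idx <- match(df$dose_mg, model$doses$label_mg)
    if (anyNA(idx))
      stop("unknown dose_mg in row(s) ",
           paste(which(is.na(idx)), collapse = ", "), " of ", path)
  } else idx <- rep(1L, nrow(df))
  out <- tox_obs(idx, df$dlt, patient_id = df$patient_id, model = model)
  out$dose_mg <- df$dose_mg
  out
}

#' Write dose/DLT observations
#'
#' @param obs a `tox_obs` data frame (with a `dose_mg` column).
#' @param path output CSV path.
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(patient_id = obs$patient_id, dose_mg = obs$dose_mg,
                   dlt = obs$dlt, enrolment_order = seq_len(nrow(obs)))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read device series and patient metadata tables
#'
#' `path_series` holds one row per patient-day with columns `patient_id`,
#' `day` and the device variables (`mpap`, `cardiac_output`, `sbp`, `dbp`,
#' `night_hr`, `day_hr`, `activity_min`); `path_patients` holds one row per
#' patient with `patient_id`, `drug_start`, `drug_stop`, `pawp_baseline`,
#' `instrumented` and optional `baseline_start`/`baseline_end`. Orphan
#' series rows, duplicate patient-days and stop-before-start dates are
#' rejected with informative errors.
#'
#' @param path_series,path_patients CSV file paths.
#' @return list of `patient_series`.
#' @export
read_series <- function(path_series, path_patients) {
  ser <- utils::read.csv(path_series, stringsAsFactors = FALSE)
  pat <- utils::read.csv(path_patients, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "day") %in% names(ser)))
    stop("series table needs 'patient_id' and 'day' columns")
  if (!all(c("patient_id", "drug_start") %in% names(pat)))
    stop("patient table needs 'patient_id' and 'drug_start' columns")
  orphan <- setdiff(ser$patient_id, pat$patient_id)
  if (length(orphan))
    stop("series rows for unknown patient(s): ",
         paste(orphan, collapse = ", "))
  dup <- duplicated(ser[c("patient_id", "day")])
  if (any(dup)) {
    d1 <- ser[which(dup)[1], ]
    stop("duplicate day ", d1$day, " for patient ", d1$patient_id)
  }
  ser$day <- as.Date(ser$day)
  lapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    start <- as.Date(p$drug_start)
    stop_d <- if (!is.null(p$drug_stop) && !is.na(p$drug_stop) &&
                  nzchar(p$drug_stop)) as.Date(p$drug_stop) else
      as.Date(NA)
    if (!is.na(stop_d) && stop_d < start)
      stop("drug stop before start for patient ", p$patient_id)
    bw <- if (all(c("baseline_start", "baseline_end") %in% names(pat)) &&
              !is.na(p$baseline_start))
      c(as.Date(p$baseline_start), as.Date(p$baseline_end)) else NULL
    days <- ser[ser$patient_id == p$patient_id,
                setdiff(names(ser), "patient_id"), drop = FALSE]
    patient_series(p$patient_id, days, drug_start = start,
                   drug_stop = stop_d, baseline_window = bw,
                   pawp_baseline = if ("pawp_baseline" %in% names(pat))
                     p$pawp_baseline else NA,
                   instrumented = if ("instrumented" %in% names(pat))
                     as.logical(p$instrumented) else TRUE)
  })
}

#' Write device series and patient metadata tables
#'
#' Inverse of [read_series()]: round-tripping a written cohort reproduces
#' the same structures.
#'
#' @param series list of `patient_series`.
#' @param path_series,path_patients output CSV paths.
#' @export
write_series <- function(series, path_series, path_patients) {
  ser <- do.call(rbind, lapply(series, function(p)
    cbind(patient_id = p$patient_id, p$days)))
  pat <- do.call(rbind, lapply(series, function(p)
    data.frame(patient_id = p$patient_id,
               drug_start = as.character(p$drug_start),
               drug_stop = if (is.na(p$drug_stop)) "" else
                 as.character(p$drug_stop),
               baseline_start = as.character(p$baseline_window[1]),
               baseline_end = as.character(p$baseline_window[2]),
               pawp_baseline = p$pawp_baseline,
               instrumented = p$instrumented,
               stringsAsFactors = FALSE)))
  utils::write.csv(ser, path_series, row.names = FALSE, na = "")
  utils::write.csv(pat, path_patients, row.names = FALSE, na = "")
  invisible(c(path_series, path_patients))
}

# Internal: md5 of the canonical JSON encoding of a config list.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline: synthesis, dose finding, hemodynamics
#'
#' Executes, from one configuration list (or JSON file): (1) synthetic
#' cohort generation; (2) a CRM replay of the cohort's dose/DLT record and
#' an operating-characteristics simulation; (3) the hemodynamics analysis
#' (cohort curves on and off drug, stability times with Kaplan-Meier
#' medians, withdrawal alerts, paired endpoint change, exposure-response).
#' Writes tidy CSV tables plus a JSON summary carrying the package
#' version, the seed and a hash of the configuration; identical
#' config + seed give identical bundles.
#'
#' Config elements (all optional except `seed`): `crm` (dose_mg, skeleton,
#' prior_shape, prior_rate, target), `design` (n_crm, first_dose_index,
#' extension_doses), `synth` (arguments of [sim_cohort_config()]),
#' `simulate` (n_sims, true_tox), `analysis` (delta, k, w,
#' alert_threshold, conf, steady_window), `out_dir`.
#'
#' @param config list or path to a JSON file.
#' @return (invisibly) the results bundle: list with `summary`, `cohort`,
#'   `replay`, `oc`, `curves`, `stability`, `alerts`, `endpoints`,
#'   `exposure`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$seed)) stop("config error: 'seed' is required")
  an <- config$analysis %||% list()
  delta <- an$delta %||% 0.15
  kk <- an$k %||% 6; ww <- an$w %||% 7
  alert_thr <- an$alert_threshold %||% 0.10
  conf <- an$conf %||% 0.95
  steady <- an$steady_window %||% c(50, 60)
  if (delta <= 0 || alert_thr < 0 || kk > ww)
    stop("config error: thresholds invalid (delta > 0, k <= w required)")
  if (conf <= 0 || conf >= 1) stop("config error: conf must be in (0,1)")
  out_dir <- config$out_dir %||% tempfile("doseflow_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))

  crm_cfg <- config$crm %||% list()
  model <- stage("crm", crm_model(
    dose_mg = crm_cfg$dose_mg %||% c(100, 200, 300, 400),
    skeleton = crm_cfg$skeleton %||% c(0.05, 0.10, 0.20, 0.35),
    prior_shape = crm_cfg$prior_shape %||% 1,
    prior_rate = crm_cfg$prior_rate %||% 1,
    target = crm_cfg$target %||% 0.20))

  # --- synthesis -----------------------------------------------------
  sy <- config$synth %||% list()
  cohort <- stage("synth", {
    cc <- sim_cohort_config(
      n_instrumented = sy$n_instrumented %||% 13,
      n_snapshot = sy$n_snapshot %||% 4,
      n_baseline_days = sy$n_baseline_days %||% 30,
      treatment_days = sy$treatment_days %||% 60,
      followup_days = sy$followup_days %||% 60,
      model = model,
      fixed_dose_mg = sy$fixed_dose_mg,
      seed = config$seed)
    generate_cohort(cc)
  })
  stage("synth", {
    write_series(cohort$series, file.path(out_dir, "series.csv"),
                 file.path(out_dir, "patients.csv"))
    write_observations(cohort$toxicity,
                       file.path(out_dir, "observations.csv"))
  })

  # --- dose finding --------------------------------------------------
  replay <- stage("crm", replay_trial(model, cohort$toxicity))
  final <- replay[[length(replay)]]
  oc <- NULL
  if (!is.null(config$simulate)) {
    oc <- stage("simulate", {
      sc <- if (!is.null(config$simulate$true_tox))
        crm_scenario(config$simulate$true_tox) else calibration_scenario()
      m_oc <- if (!is.null(config$simulate$true_tox)) model else
        crm_model(skeleton = sc$true_tox)
      operating_characteristics(
        m_oc, trial_design(n_crm = config$design$n_crm %||% 13),
        sc, n_sims = config$simulate$n_sims %||% 1000,
        seed = config$seed)
    })
  }

  # --- hemodynamics --------------------------------------------------
  curves <- stage("hemodynamics", list(
    tpr_start = cohort_curve(cohort$series, "tpr", "start", "absolute",
                             conf = conf),
    tpr_start_pct = cohort_curve(cohort$series, "tpr", "start", "percent",
                                 conf = conf),
    tpr_stop = cohort_curve(cohort$series, "tpr", "stop", "absolute",
                            conf = conf),
    night_hr = cohort_curve(cohort$series, "night_hr", "start", "absolute",
                            conf = conf),
    activity = cohort_curve(cohort$series, "activity_min", "start",
                            "absolute", conf = conf)))
  for (nm in names(curves))
    utils::write.csv(curves[[nm]],
                     file.path(out_dir, paste0("curve_", nm, ".csv")),
                     row.names = FALSE, na = "")

  stability <- stage("hemodynamics", {
    on_d <- lapply(cohort$series, patient_stability, phase = "onset",
                   delta = delta, k = kk, w = ww)
    off_d <- lapply(cohort$series, patient_stability, phase = "withdrawal",
                    delta = delta, k = kk, w = ww)
    list(onset = km_summary(vapply(on_d, `[[`, 0, "time"),
                            vapply(on_d, `[[`, TRUE, "event"), conf = conf),
         withdrawal = km_summary(vapply(off_d, `[[`, 0, "time"),
                                 vapply(off_d, `[[`, TRUE, "event"),
                                 conf = conf))
  })

  alerts <- stage("hemodynamics", {
    a <- lapply(cohort$series, withdrawal_alert, threshold = alert_thr)
    data.frame(patient_id = vapply(cohort$series, `[[`, "", "patient_id"),
               alert_day = vapply(a, function(x)
                 if (is.na(x$day[1])) NA_character_ else
                   as.character(x$day), ""),
               baseline_mpap = vapply(a, `[[`, 0, "baseline"))
  })
  utils::write.csv(alerts, file.path(out_dir, "alerts.csv"),
                   row.names = FALSE, na = "")

  # per-patient steady-state percent TPR change (mean over the steady
  # window of the percent-mode baseline-adjusted series)
  pct <- stage("hemodynamics", vapply(cohort$series, function(p) {
    s <- baseline_adjust(p, "tpr", "start", "percent")
    mean(s$value[s$rel_day >= steady[1] & s$rel_day <= steady[2]],
         na.rm = TRUE)
  }, numeric(1)))
  names(pct) <- vapply(cohort$series, `[[`, "", "patient_id")

  endpoints <- stage("hemodynamics", {
    base_tpr <- vapply(cohort$series, function(p)
      attr(baseline_adjust(p, "tpr", "start"), "baseline"), numeric(1))
    follow_tpr <- base_tpr * (1 + pct / 100)
    list(tpr = endpoint_change(base_tpr, follow_tpr, "paired-t",
                               variable = "TPR (WU)", conf = conf))
  })

  doses <- vapply(cohort$series, function(p)
    p$dose_history$dose_mg[1], numeric(1))
  names(doses) <- names(pct)
  expo <- stage("hemodynamics",
                exposure_response(doses, cohort$exposure, pct))
  utils::write.csv(expo$table, file.path(out_dir, "exposure_response.csv"),
                   row.names = FALSE, na = "")

  summary <- list(
    package = "doseflow",
    version = as.character(utils::packageVersion("doseflow")),
    seed = config$seed,
    config_hash = .config_hash(config),
    crm = list(final_recommendation = final$recommended_index,
               recommended_dose_mg =
                 model$doses$label_mg[final$recommended_index],
               mean_tox = final$mean_tox, median_tox = final$median_tox),
    oc = if (!is.null(oc)) list(
      prob_target_selected = oc$prob_target_selected,
      selection_prob = oc$selection_prob),
    stability = list(onset_median = stability$onset$median,
                     withdrawal_median = stability$withdrawal$median),
    tpr_change = list(mean_pct = unname(mean(pct, na.rm = TRUE)),
                      paired_t = endpoints$tpr[
                        c("change", "ci_lo", "ci_hi", "p_value")]),
    exposure_response_rho = expo$rho)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(summary = summary, cohort = cohort, replay = replay,
                 oc = oc, curves = curves, stability = stability,
                 alerts = alerts, endpoints = endpoints,
                 exposure = expo, out_dir = out_dir))
}
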