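# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis pipeline assumes: a
# small PAH cohort on a once-daily tyrosine-kinase inhibitor with
# dose-proportional exposure (log-normal interindividual variability), a
# saturating exposure-effect link, mono-exponential onset of a steady-state
# TPR reduction on drug and a slower mono-exponential return after
# withdrawal, parallel night-heart-rate and activity responses, Gaussian
# device noise and missing days. Toxicity (4-week DLT) is generated
# independently of hemodynamics from an assumed dose-toxicity scenario.

#' Per-patient simulation parameters
#'
#' Defaults describe a typical instrumented patient of the cohort the
#' generator emulates: baseline TPR 11.7 WU and mean PAP 52.9 mmHg (cardiac
#' output follows as mPAP/TPR), a steady-state TPR reduction of 20.3% for
#' the typical 200 mg patient via a saturating (Emax-type) exposure-effect
#' link, onset time constant 9 days and offset 15 days, night heart rate
#' falling 2.7 bpm and daily activity rising 14.3 min on drug, device-scale
#' noise and 5% missing days.
#'
#' @param dose_mg assigned once-daily dose, mg.
#' @param baseline_tpr baseline total pulmonary resistance, WU.
#' @param baseline_mpap baseline mean PAP, mmHg.
#' @param baseline_map baseline mean systemic arterial pressure, mmHg.
#' @param pulse_pressure systemic pulse pressure, mmHg (SBP - DBP).
#' @param baseline_night_hr baseline night heart rate, bpm.
#' @param baseline_activity baseline daily activity, minutes.
#' @param pawp_baseline catheter wedge pressure, mmHg.
#' @param effect_max maximal fractional TPR reduction (Emax); the default
#'   0.253750 puts the typical 200 mg patient (80% of Emax) at 0.203.
#' @param auc50 AUC at half-maximal effect, ug.h/L.
#' @param k_auc exposure per mg at unit clearance, ug.h/L per mg.
#' @param sigma_ln log-scale SD of the clearance multiplier.
#' @param clearance_multiplier fixed multiplier; NULL to draw log-normally.
#' @param link `"emax"` or `"linear"` exposure-effect link.
#' @param tau_on,tau_off onset and offset time constants, days.
#' @param hr_effect night-heart-rate reduction at steady state, bpm.
#' @param activity_effect activity increase at steady state, minutes.
#' @param sys_ratio systemic-to-pulmonary effect ratio: the fractional MAP
#'   reduction is `sys_ratio` times the fractional TPR reduction.
#' @param noise_tpr,noise_hr,noise_activity,noise_bp Gaussian measurement
#'   SDs (WU, bpm, minutes, mmHg).
#' @param missing_prob i.i.d. probability that a device day is missing.
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(dose_mg = 200,
                       baseline_tpr = 11.7, baseline_mpap = 52.9,
                       baseline_map = 83.6, pulse_pressure = 45,
                       baseline_night_hr = 70, baseline_activity = 150,
                       pawp_baseline = 10.3,
                       effect_max = 0.253750, auc50 = 5000,
                       k_auc = 100, sigma_ln = 0.3,
                       clearance_multiplier = NULL,
                       link = c("emax", "linear"),
                       tau_on = 9, tau_off = 15,
                       hr_effect = 2.7, activity_effect = 14.3,
                       sys_ratio = 0.41,
                       noise_tpr = 0.3, noise_hr = 1.5,
                       noise_activity = 5, noise_bp = 3,
                       missing_prob = 0.05) {
  link <- match.arg(link)
  if (effect_max < 0 || effect_max >= 1)
    stop("effect_max must lie in [0, 1)")
  if (tau_on <= 0 || tau_off <= 0) stop("time constants must be positive")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must lie in [0, 1)")
  structure(as.list(environment()), class = "sim_params")
}

#' Steady-state exposure from dose
#'
#' AUC = k_auc * dose / clearance multiplier; the multiplier is log-normal
#' (median 1, log-SD `sigma_ln`), so exposure is dose proportional for a
#' given patient and varies between patients.
#'
#' @param dose_mg dose in mg (vectorized).
#' @param k_auc exposure per mg at unit clearance.
#' @param sigma_ln log-scale SD of the clearance multiplier.
#' @param clearance_multiplier optional fixed multiplier(s); when NULL one
#'   is drawn per dose entry from the current RNG stream.
#' @return steady-state AUC, ug.h/L.
#' @export
generate_exposure <- function(dose_mg, k_auc = 100, sigma_ln = 0.3,
                              clearance_multiplier = NULL) {
  if (is.null(clearance_multiplier))
    clearance_multiplier <- exp(stats::rnorm(length(dose_mg), 0, sigma_ln))
  k_auc * dose_mg / clearance_multiplier
}

#' Fractional steady-state TPR reduction from exposure
#'
#' Saturating link `effect_max * auc / (auc50 + auc)` (default) or a linear
#' link through the origin matched to the saturating one at the typical
#' 200 mg exposure, capped at `effect_max`.
#'
#' @param auc steady-state AUC, ug.h/L.
#' @param params a `sim_params`.
#' @return fractional reduction in (0, effect_max\].
#' @export
effect_from_auc <- function(auc, params) {
  if (params$link == "emax")
    params$effect_max * auc / (params$auc50 + auc)
  else
    pmin(params$effect_max, params$effect_max * auc / (5 * params$auc50))
}

# Internal: onset/offset kinetic fraction at day t (t = 0 is drug start),
# with dosing stopping after day t_stop (NULL/Inf = never stops).
.kinetic_fraction <- function(t, tau_on, tau_off, t_stop = Inf) {
  f <- ifelse(t < 0, 0, 1 - exp(-t / tau_on))
  if (is.finite(t_stop)) {
    f_stop <- 1 - exp(-t_stop / tau_on)
    off <- t > t_stop
    f[off] <- f_stop * exp(-(t[off] - t_stop) / tau_off)
  }
  f
}

#' Simulate one patient's daily device series
#'
#' Latent TPR follows `baseline * (1 - E * f(t))` where `E` is the
#' patient's fractional steady-state reduction from [effect_from_auc()] and
#' `f(t)` rises as `1 - exp(-t/tau_on)` on drug and decays as
#' `exp(-(t - t_stop)/tau_off)` after withdrawal. Daily observed TPR is
#' latent plus Gaussian noise; mean PAP is observed TPR times the patient's
#' (constant) cardiac output, so TPR recomputed from the emitted mPAP and
#' cardiac output reproduces the noisy TPR exactly. Night heart rate,
#' activity and systemic pressures follow the same kinetics with their own
#' effect sizes and noise. Device days are dropped i.i.d. with
#' `missing_prob`.
#'
#' @param params a `sim_params`.
#' @param patient_id identifier.
#' @param n_baseline_days pre-drug days recorded.
#' @param treatment_days days on drug (day 0 = first dose; the stop date is
#'   `start_date + treatment_days`).
#' @param followup_days post-withdrawal days recorded; 0 for an on-drug
#'   series with no withdrawal phase.
#' @param start_date Date of first dose.
#' @param auc optional pre-drawn steady-state AUC; when NULL it is drawn
#'   via [generate_exposure()].
#' @return a `patient_series`; the realized `auc` and true fractional
#'   effect `E` are attached as attributes.
#' @export
generate_patient_series <- function(params, patient_id = "P1",
                                    n_baseline_days = 30,
                                    treatment_days = 60,
                                    followup_days = 60,
                                    start_date = as.Date("2021-01-01"),
                                    auc = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(auc))
    auc <- generate_exposure(params$dose_mg, params$k_auc, params$sigma_ln,
                             params$clearance_multiplier)
  E <- effect_from_auc(auc, params)
  t_stop <- if (followup_days > 0) treatment_days else Inf
  t <- seq.int(-n_baseline_days, treatment_days + followup_days)
  f <- .kinetic_fraction(t, params$tau_on, params$tau_off, t_stop)
  n <- length(t)
  co <- params$baseline_mpap / params$baseline_tpr
  tpr_obs <- params$baseline_tpr * (1 - E * f) +
    stats::rnorm(n, 0, params$noise_tpr)
  mpap <- tpr_obs * co
  map <- params$baseline_map * (1 - params$sys_ratio * E * f) +
    stats::rnorm(n, 0, params$noise_bp)
  dbp <- map - params$pulse_pressure / 3
  sbp <- dbp + params$pulse_pressure
  night_hr <- params$baseline_night_hr - params$hr_effect * f +
    stats::rnorm(n, 0, params$noise_hr)
  day_hr <- night_hr + 12 + stats::rnorm(n, 0, params$noise_hr)
  activity <- pmax(0, params$baseline_activity + params$activity_effect * f +
                     stats::rnorm(n, 0, params$noise_activity))
  keep <- stats::runif(n) >= params$missing_prob
  days <- data.frame(day = start_date + t,
                     mpap = mpap, cardiac_output = co,
                     sbp = sbp, dbp = dbp,
                     night_hr = night_hr, day_hr = day_hr,
                     activity_min = activity)[keep, , drop = FALSE]
  ps <- patient_series(patient_id, days,
                       drug_start = start_date,
                       drug_stop = if (is.finite(t_stop))
                         start_date + treatment_days else NA,
                       baseline_window = c(start_date - n_baseline_days,
                                           start_date - 1),
                       dose_history = data.frame(date = start_date,
                                                 dose_mg = params$dose_mg),
                       pawp_baseline = params$pawp_baseline)
  attr(ps, "auc") <- auc
  attr(ps, "true_effect") <- E
  ps
}

#' Cohort-level simulation configuration
#'
#' @param n_instrumented patients with daily device series (default 13).
#' @param n_snapshot patients with baseline/follow-up catheter values only
#'   (default 4), enrolled at the two lowest dose levels.
#' @param n_baseline_days,treatment_days,followup_days series layout, days.
#' @param model a `crm_model` used to assign CRM doses.
#' @param scenario a `crm_scenario` for the DLT draw; defaults to the
#'   model's skeleton read as the true curve.
#' @param fixed_dose_mg when non-NULL, all instrumented patients receive
#'   this dose instead of CRM-driven assignments (used e.g. for
#'   fixed-dose parameter-recovery experiments).
#' @param params_template a `sim_params` providing the typical-patient
#'   values; per-patient baselines are drawn around it.
#' @param baseline_sd_tpr,baseline_sd_co,baseline_sd_hr,baseline_sd_act
#'   between-patient SDs of baseline TPR (WU), cardiac output (L/min),
#'   night HR (bpm) and activity (min).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_instrumented = 13, n_snapshot = 4,
                              n_baseline_days = 30, treatment_days = 60,
                              followup_days = 60,
                              model = crm_model(), scenario = NULL,
                              fixed_dose_mg = NULL,
                              params_template = sim_params(),
                              baseline_sd_tpr = 3, baseline_sd_co = 0.7,
                              baseline_sd_hr = 8, baseline_sd_act = 40,
                              seed = 1) {
  if (n_instrumented < 0 || n_snapshot < 0) stop("counts must be >= 0")
  if (is.null(scenario))
    scenario <- crm_scenario(model$doses$standardized_dose,
                             name = "skeleton-as-truth")
  structure(as.list(environment()), class = "sim_cohort_config")
}

#' Generate a full synthetic cohort
#'
#' Produces `n_instrumented` patients with daily device series plus
#' `n_snapshot` patients with baseline/follow-up values only. Dose
#' assignments and 4-week DLT outcomes for the instrumented patients come
#' from one simulated sequential CRM trial under `config$scenario` (or a
#' fixed dose when `config$fixed_dose_mg` is set); snapshot patients are
#' assigned alternately to the two lowest dose levels, mirroring a
#' lower-dose extension cohort. Hemodynamic series are generated
#' independently of toxicity. Fully reproducible from `config$seed`.
#'
#' @param config a `sim_cohort_config`.
#' @return list with `series` (list of `patient_series`), `toxicity` (a
#'   `tox_obs` data frame with dose labels), `exposure` (named AUC vector),
#'   `true_effect` (named fractional reductions), `snapshot` (data frame of
#'   baseline/follow-up TPR for non-instrumented patients) and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  tpl <- config$params_template
  model <- config$model
  .with_seed(config$seed, {
    n_i <- config$n_instrumented
    n_s <- config$n_snapshot
    # dose assignment + DLTs
    if (is.null(config$fixed_dose_mg)) {
      des <- trial_design(n_crm = max(n_i, 1),
                          extension_doses = rep(c(1L, 2L),
                                                length.out = n_s))
      tr <- simulate_trial(model, des, config$scenario,
                           seed = sample.int(2^30, 1))
      dose_idx <- tr$assignments[seq_len(n_i)]
      dlt <- tr$outcomes[seq_len(n_i)]
      snap_idx <- tr$ext_assignments
      snap_dlt <- tr$ext_outcomes
    } else {
      dose_idx <- rep(match(config$fixed_dose_mg, model$doses$label_mg),
                      n_i)
      if (any(is.na(dose_idx))) stop("fixed_dose_mg not on the dose grid")
      dlt <- stats::rbinom(n_i, 1, config$scenario$true_tox[dose_idx])
      snap_idx <- rep(c(1L, 2L), length.out = n_s)
      snap_dlt <- stats::rbinom(n_s, 1,
                                config$scenario$true_tox[snap_idx])
    }
    ids <- sprintf("P%02d", seq_len(n_i + n_s))
    series <- vector("list", n_i)
    auc_map <- numeric(0)
    eff_map <- numeric(0)
    for (i in seq_len(n_i)) {
      p <- tpl
      p$dose_mg <- model$doses$label_mg[dose_idx[i]]
      p$baseline_tpr <- max(5, stats::rnorm(1, tpl$baseline_tpr,
                                            config$baseline_sd_tpr))
      co <- max(2.5, stats::rnorm(1, tpl$baseline_mpap / tpl$baseline_tpr,
                                  config$baseline_sd_co))
      p$baseline_mpap <- p$baseline_tpr * co
      p$baseline_night_hr <- stats::rnorm(1, tpl$baseline_night_hr,
                                          config$baseline_sd_hr)
      p$baseline_activity <- max(30, stats::rnorm(1, tpl$baseline_activity,
                                                  config$baseline_sd_act))
      ps <- generate_patient_series(
        p, patient_id = ids[i],
        n_baseline_days = config$n_baseline_days,
        treatment_days = config$treatment_days,
        followup_days = config$followup_days)
      series[[i]] <- ps
      auc_map[ids[i]] <- attr(ps, "auc")
      eff_map[ids[i]] <- attr(ps, "true_effect")
    }
    # snapshot patients: catheter TPR at baseline and end of treatment
    snap <- NULL
    if (n_s > 0) {
      snap_rows <- lapply(seq_len(n_s), function(j) {
        id <- ids[n_i + j]
        dose <- model$doses$label_mg[snap_idx[j]]
        auc <- generate_exposure(dose, tpl$k_auc, tpl$sigma_ln,
                                 tpl$clearance_multiplier)
        E <- effect_from_auc(auc, tpl)
        b <- max(5, stats::rnorm(1, tpl$baseline_tpr,
                                 config$baseline_sd_tpr))
        f_end <- .kinetic_fraction(config$treatment_days, tpl$tau_on,
                                   tpl$tau_off)
        data.frame(patient_id = id, dose_mg = dose,
                   tpr_baseline = b + stats::rnorm(1, 0, tpl$noise_tpr),
                   tpr_followup = b * (1 - E * f_end) +
                     stats::rnorm(1, 0, tpl$noise_tpr),
                   auc = auc, stringsAsFactors = FALSE)
      })
      snap <- do.call(rbind, snap_rows)
      auc_map[snap$patient_id] <- snap$auc
    }
    tox <- tox_obs(c(dose_idx, snap_idx), c(dlt, snap_dlt),
                   patient_id = ids, model = model)
    tox$dose_mg <- model$doses$label_mg[tox$dose_index]
    list(series = series, toxicity = tox, exposure = auc_map,
         true_effect = eff_map, snapshot = snap, config = config)
  })
}
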