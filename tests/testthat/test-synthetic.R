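# Synthetic cohort generator: exposure, kinetics, cohort structure and
# recovery of the generating parameters by the analysis pipeline.

steady_pct <- function(coh, window = c(50, 60)) {
  vapply(coh$series, function(p) {
    s <- baseline_adjust(p, "tpr", "start", "percent")
    mean(s$value[s$rel_day >= window[1] & s$rel_day <= window[2]],
         na.rm = TRUE)
  }, numeric(1))
}

test_that("exposure is dose proportional with log-normal interindividual spread", {
  expect_equal(generate_exposure(400, clearance_multiplier = 1),
               4 * generate_exposure(100, clearance_multiplier = 1))
  set.seed(1)
  expect_equal(generate_exposure(200, sigma_ln = 0), 20000)
  # realized coefficient of variation matches the log-normal closed form
  set.seed(2)
  auc <- generate_exposure(rep(200, 20000), sigma_ln = 0.3)
  cv_true <- sqrt(exp(0.3^2) - 1)
  expect_equal(sd(auc) / mean(auc), cv_true, tolerance = 0.03)
  # typical 200 mg patient sits at 80% of Emax: fractional effect 0.203
  p <- sim_params()
  expect_equal(effect_from_auc(20000, p), 0.203)
  expect_true(all(diff(effect_from_auc(c(5000, 10000, 20000, 40000), p)) > 0))
})

test_that("patient series follow the exponential onset/offset kinetics", {
  # null effect, no noise: every day equals baseline
  p0 <- sim_params(effect_max = 0, sigma_ln = 0, noise_tpr = 0,
                   noise_hr = 0, noise_activity = 0, noise_bp = 0,
                   missing_prob = 0)
  s0 <- generate_patient_series(p0)
  tpr0 <- compute_tpr(s0$days$mpap, s0$days$cardiac_output)
  expect_true(all(abs(tpr0 - p0$baseline_tpr) < 1e-10))
  # typical 200 mg patient, noiseless: steady state at 79.7% of baseline
  p1 <- sim_params(sigma_ln = 0, noise_tpr = 0, noise_hr = 0,
                   noise_activity = 0, noise_bp = 0, missing_prob = 0)
  s1 <- generate_patient_series(p1, treatment_days = 120, followup_days = 0)
  tpr1 <- compute_tpr(s1$days$mpap, s1$days$cardiac_output)
  expect_equal(tail(tpr1, 1) / p1$baseline_tpr, 0.797, tolerance = 1e-3)
  expect_equal(attr(s1, "true_effect"), 0.203)
  # night HR declines by its configured effect; activity rises
  expect_equal(tail(s1$days$night_hr, 1),
               p1$baseline_night_hr - p1$hr_effect, tolerance = 1e-3)
  expect_equal(tail(s1$days$activity_min, 1),
               p1$baseline_activity + p1$activity_effect, tolerance = 1e-2)
  # effectively infinite offset time constant: no post-withdrawal return
  p2 <- sim_params(sigma_ln = 0, noise_tpr = 0, noise_hr = 0,
                   noise_activity = 0, noise_bp = 0, missing_prob = 0,
                   tau_off = 1e9)
  s2 <- generate_patient_series(p2, treatment_days = 60, followup_days = 60)
  tpr2 <- compute_tpr(s2$days$mpap, s2$days$cardiac_output)
  f60 <- 1 - exp(-60 / p2$tau_on)
  expect_equal(tail(tpr2, 1),
               p2$baseline_tpr * (1 - 0.203 * f60), tolerance = 1e-6)
})

test_that("cohorts have the configured structure and are reproducible", {
  cfg <- sim_cohort_config(seed = 4)
  coh <- generate_cohort(cfg)
  expect_length(coh$series, 13)
  expect_identical(nrow(coh$snapshot), 4L)
  expect_identical(nrow(coh$toxicity), 17L)
  expect_true(all(names(coh$exposure) ==
                    c(sapply(coh$series, `[[`, "patient_id"),
                      coh$snapshot$patient_id)))
  coh2 <- generate_cohort(cfg)
  expect_identical(serialize(coh$toxicity, NULL),
                   serialize(coh2$toxicity, NULL))
  expect_identical(coh$series[[5]]$days, coh2$series[[5]]$days)
  expect_false(identical(coh$series[[5]]$days,
                         generate_cohort(sim_cohort_config(seed = 5))$series[[5]]$days))
})

test_that("noiseless cohorts recover the generating effect within 1 percentage point", {
  tpl <- sim_params(sigma_ln = 0, noise_tpr = 0, noise_hr = 0,
                    noise_activity = 0, noise_bp = 0, missing_prob = 0)
  coh <- generate_cohort(sim_cohort_config(fixed_dose_mg = 200, seed = 5,
                                           params_template = tpl))
  est <- mean(steady_pct(coh))
  expect_lt(abs(est - (-20.3)), 1)
})

test_that("noiseless stability detection matches the closed-form event day", {
  p <- sim_params(sigma_ln = 0, noise_tpr = 0, noise_hr = 0,
                  noise_activity = 0, noise_bp = 0, missing_prob = 0)
  s <- generate_patient_series(p, treatment_days = 60, followup_days = 0)
  st <- patient_stability(s, "onset")
  # daily change of the 3-day-averaged exponential drop falls below delta
  # at t* = tau * ln(B*E*(e^(3/tau) - 1) / (3*delta)); the first window
  # with >= k sub-threshold changes then completes k - 1 days later
  BE <- p$baseline_tpr * 0.203
  tstar <- p$tau_on * log(BE * (exp(3 / p$tau_on) - 1) / (3 * 0.15))
  analytic <- ceiling(tstar) + 5
  expect_true(st$event)
  expect_lte(abs(st$time - analytic), 3)
})

test_that("generated cohorts show a negative exposure-response correlation at low noise", {
  tpl <- sim_params(noise_tpr = 0.01, missing_prob = 0)
  coh <- generate_cohort(sim_cohort_config(fixed_dose_mg = 200, seed = 6,
                                           params_template = tpl))
  pct <- steady_pct(coh)
  doses <- vapply(coh$series, function(p) p$dose_history$dose_mg[1],
                  numeric(1))
  names(doses) <- names(pct) <- vapply(coh$series, `[[`, "", "patient_id")
  er <- exposure_response(doses, coh$exposure, pct)
  expect_lt(er$rho, -0.9)
})
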