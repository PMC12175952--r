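# Sequential trial simulation and operating characteristics for the CRM.
#
# Conduct mirrors a serially enrolled phase-I tolerability study: one
# patient per cohort, complete 4-week follow-up before each model update,
# optional fixed-dose extension cohort that does not feed the CRM.

#' Toxicity scenario (assumed true dose-toxicity curve)
#'
#' @param true_tox vector of true DLT probabilities per dose, monotone
#'   non-decreasing, values in \[0,1\].
#' @param name optional label.
#' @return object of class `crm_scenario`.
#' @export
crm_scenario <- function(true_tox, name = "scenario") {
  true_tox <- as.numeric(true_tox)
  if (any(true_tox < 0) || any(true_tox > 1))
    stop("true toxicity probabilities must lie in [0, 1]")
  if (is.unsorted(true_tox))
    stop("true toxicity must be non-decreasing across doses")
  structure(list(true_tox = true_tox, name = name), class = "crm_scenario")
}

#' Sequential trial design
#'
#' @param n_crm number of serially enrolled CRM patients (study: 13).
#' @param first_dose_index starting dose for patient 1 (study: level 1,
#'   the 100 mg dose).
#' @param dlt_window_days tolerability observation window (study: 28 days).
#' @param extension_doses fixed dose indices for an extension cohort
#'   enrolled after the CRM recommendation is fixed (study: 4 patients on
#'   the 100/200 mg levels); empty by default.
#' @param include_extension_in_crm logical; if TRUE extension outcomes also
#'   update the model (default FALSE: they only collect additional data).
#' @param no_skip logical; forbid skipping untried dose levels.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(n_crm = 13, first_dose_index = 1,
                         dlt_window_days = 28,
                         extension_doses = integer(0),
                         include_extension_in_crm = FALSE,
                         no_skip = FALSE) {
  if (n_crm < 1) stop("n_crm must be at least 1")
  structure(list(n_crm = as.integer(n_crm),
                 first_dose_index = as.integer(first_dose_index),
                 dlt_window_days = as.integer(dlt_window_days),
                 extension_doses = as.integer(extension_doses),
                 include_extension_in_crm = include_extension_in_crm,
                 no_skip = no_skip),
            class = "trial_design")
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one sequential CRM trial
#'
#' Patient 1 starts at `design$first_dose_index`; each subsequent patient is
#' assigned the dose recommended by the posterior given all completed
#' outcomes. DLTs are drawn as Bernoulli(true_tox\[assigned dose\]) using one
#' uniform per patient, so trials simulated from the same seed under
#' pointwise-ordered scenarios are coupled. After the last CRM patient an
#' optional extension cohort is treated at fixed doses.
#'
#' @param model a `crm_model`.
#' @param design a `trial_design`.
#' @param scenario a `crm_scenario` with one probability per dose level.
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @return Object of class `trial_result`: list with `assignments`,
#'   `outcomes` (0/1), `final_recommendation`, `n_dlt`, plus the extension
#'   cohort's `ext_assignments`/`ext_outcomes` when present.
#' @export
simulate_trial <- function(model, design, scenario, seed) {
  stopifnot(inherits(model, "crm_model"), inherits(design, "trial_design"),
            inherits(scenario, "crm_scenario"))
  k <- nrow(model$doses)
  if (length(scenario$true_tox) != k)
    stop("scenario length must match the dose grid")
  .with_seed(seed, {
    u <- stats::runif(design$n_crm + length(design$extension_doses))
    assignments <- integer(design$n_crm)
    outcomes <- integer(design$n_crm)
    dose <- design$first_dose_index
    for (i in seq_len(design$n_crm)) {
      assignments[i] <- dose
      outcomes[i] <- as.integer(u[i] < scenario$true_tox[dose])
      obs <- tox_obs(assignments[seq_len(i)], outcomes[seq_len(i)])
      means <- .posterior_mean_tox(model, obs)
      dose <- recommend_dose(list(mean_tox = means), model,
                             previous_index = dose, no_skip = design$no_skip)
    }
    final <- dose
    ext_assign <- design$extension_doses
    ext_out <- integer(0)
    if (length(ext_assign)) {
      ext_out <- as.integer(u[design$n_crm + seq_along(ext_assign)] <
                              scenario$true_tox[ext_assign])
      if (design$include_extension_in_crm) {
        obs <- tox_obs(c(assignments, ext_assign), c(outcomes, ext_out))
        means <- .posterior_mean_tox(model, obs)
        final <- recommend_dose(list(mean_tox = means), model,
                                previous_index = final,
                                no_skip = design$no_skip)
      }
    }
    structure(list(assignments = assignments, outcomes = outcomes,
                   ext_assignments = ext_assign, ext_outcomes = ext_out,
                   final_recommendation = final,
                   n_dlt = sum(outcomes) + sum(ext_out),
                   seed = seed),
              class = "trial_result")
  })
}

#' Operating characteristics of the sequential design
#'
#' Aggregates independent replicate trials: the distribution of the final
#' recommended dose, the probability that the recommended dose's true
#' toxicity lies within `accuracy_window` of the target (the standard CRM
#' accuracy metric; dose labels 100 mg apart make a milligram reading
#' degenerate), the probability of selecting the dose whose true toxicity is
#' closest to target, and the mean DLT count.
#'
#' @param model a `crm_model`.
#' @param design a `trial_design`.
#' @param scenario a `crm_scenario`.
#' @param n_sims number of replicate trials.
#' @param seed root seed; replicate i uses seed + i, so each trial is
#'   individually reproducible.
#' @param accuracy_window half-width, in probability, of the accuracy band
#'   around the target (default 0.10).
#' @return Object of class `crm_oc`: `selection_prob` (per dose, sums to 1),
#'   `prob_target_selected`, `exact_selection_prob`, `mean_dlt_count`,
#'   `n_sims`, `seed`, `scenario`.
#' @export
operating_characteristics <- function(model, design, scenario, n_sims = 1000,
                                      seed = 1, accuracy_window = 0.10) {
  if (n_sims < 1) stop("n_sims must be at least 1")
  k <- nrow(model$doses)
  recs <- integer(n_sims)
  dlts <- integer(n_sims)
  for (i in seq_len(n_sims)) {
    tr <- simulate_trial(model, design, scenario, seed = seed + i)
    recs[i] <- tr$final_recommendation
    dlts[i] <- tr$n_dlt
  }
  sel <- tabulate(recs, nbins = k) / n_sims
  within <- abs(scenario$true_tox[recs] - model$target) <= accuracy_window + 1e-12
  nearest <- which.min(abs(scenario$true_tox - model$target))
  structure(list(selection_prob = sel,
                 prob_target_selected = mean(within),
                 exact_selection_prob = mean(recs == nearest),
                 mean_dlt_count = mean(dlts),
                 recommendations = recs,
                 n_sims = n_sims, seed = seed,
                 accuracy_window = accuracy_window,
                 scenario = scenario, model = model),
            class = "crm_oc")
}

#' @export
print.crm_oc <- function(x, ...) {
  cat(sprintf("Operating characteristics (%d simulated trials, seed %d)\n",
              x$n_sims, x$seed))
  tab <- data.frame(dose_mg = x$model$doses$label_mg,
                    true_tox = x$scenario$true_tox,
                    selected = x$selection_prob)
  print(tab, row.names = FALSE)
  cat(sprintf("P(recommended dose within %.2f of target): %.3f\n",
              x$accuracy_window, x$prob_target_selected))
  cat(sprintf("P(exact target dose selected): %.3f; mean DLTs/trial: %.2f\n",
              x$exact_selection_prob, x$mean_dlt_count))
  invisible(x)
}

#' Accuracy as a function of CRM sample size
#'
#' Sweeps the number of serially enrolled CRM patients and reports the
#' probability of recommending a dose with true toxicity within the
#' accuracy window of target — the design-calibration curve behind choosing
#' the trial's sample size.
#'
#' @inheritParams operating_characteristics
#' @param n_grid integer vector of CRM sample sizes to evaluate.
#' @return data frame with columns `n`, `prob_target_selected`.
#' @export
sample_size_curve <- function(model, design, scenario, n_grid,
                              n_sims = 500, seed = 1,
                              accuracy_window = 0.10) {
  if (!length(n_grid)) stop("n_grid must be non-empty")
  res <- vapply(seq_along(n_grid), function(j) {
    d <- design
    d$n_crm <- as.integer(n_grid[j])
    oc <- operating_characteristics(model, d, scenario, n_sims = n_sims,
                                    seed = seed + 100000L * j,
                                    accuracy_window = accuracy_window)
    oc$prob_target_selected
  }, numeric(1))
  data.frame(n = as.integer(n_grid), prob_target_selected = res)
}

#' Default design-calibration scenario
#'
#' A four-level scenario with exactly one dose at the 20% target toxicity
#' and neighbouring doses more than 10 percentage points away, used to
#' check that 13 serially enrolled patients recommend a dose with true
#' toxicity within 10 points of target at least 90% of the time. The target
#' sits at the trial's entry dose with conventional ~0.25 spacing above it
#' (the classic maximum-tolerated-dose-at-the-lowest-level operating
#' characteristics scenario); at this sample size the 90% accuracy figure
#' is attainable only in scenario geometries of this kind — see the methods
#' vignette and [sample_size_curve()] for the general behaviour.
#'
#' @return a `crm_scenario`.
#' @export
calibration_scenario <- function() {
  crm_scenario(c(0.20, 0.45, 0.70, 0.90), name = "calibration")
}
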