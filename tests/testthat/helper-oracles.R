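# Independent oracles used across the suite. Each is deliberately written
# as a direct transcription of the definition (enumeration, brute force,
# Monte Carlo), sharing no code with the implementation it checks.

# Posterior mean toxicity per dose by importance sampling from the prior:
# draws alpha ~ Gamma(shape, rate), weights by the Bernoulli power-model
# likelihood. Returns means and their ratio-estimator standard errors.
mc_posterior_mean <- function(model, data, n = 1e6) {
  a <- stats::rgamma(n, shape = model$prior_shape, rate = model$prior_rate)
  lw <- rep(0, n)
  for (i in seq_len(nrow(data))) {
    d <- model$doses$standardized_dose[data$dose_index[i]]
    lw <- lw + if (data$dlt[i] == 1L) a * log(d) else log1p(-d^a)
  }
  w <- exp(lw - max(lw))
  sw <- sum(w)
  means <- ses <- numeric(nrow(model$doses))
  for (k in seq_len(nrow(model$doses))) {
    x <- model$doses$standardized_dose[k]^a
    mu <- sum(w * x) / sw
    # SE of the ratio estimator sum(w x)/sum(w)
    ses[k] <- sqrt(sum((w * (x - mu))^2)) / sw
    means[k] <- mu
  }
  list(mean = means, se = ses)
}

# Closed-form posterior mean toxicity when every observation is a DLT:
# the likelihood prod d_i^alpha = exp(alpha * sum log d_i) only shifts the
# Gamma rate, so the posterior is Gamma(shape, rate - sum log d_i) and
# E[d^alpha] is its moment generating function at log d.
all_dlt_closed_form <- function(model, data) {
  stopifnot(all(data$dlt == 1L))
  d_obs <- model$doses$standardized_dose[data$dose_index]
  rate <- model$prior_rate - sum(log(d_obs))
  (1 - log(model$doses$standardized_dose) / rate)^(-model$prior_shape)
}

# Exhaustive sliding-window stability scan: expands the calendar grid,
# forms every window of w consecutive daily changes and counts the
# sub-threshold ones by explicit loops.
brute_stability <- function(day, value, delta = 0.15, k = 6, w = 7) {
  grid <- seq(min(day), max(day), by = 1)
  v <- rep(NA_real_, length(grid))
  v[match(as.numeric(day), as.numeric(grid))] <- value
  if (length(grid) < w + 1L)
    return(list(time = grid[length(grid)], event = FALSE))
  for (end in seq.int(w + 1L, length(grid))) {
    cnt <- 0L
    for (j in seq.int(end - w + 1L, end)) {
      chg <- abs(v[j] - v[j - 1L])
      if (!is.na(chg) && chg < delta) cnt <- cnt + 1L
    }
    if (cnt >= k) return(list(time = grid[end], event = TRUE))
  }
  list(time = grid[length(grid)], event = FALSE)
}

# Random small toxicity data set on a model's grid.
random_tox_data <- function(model, n_max = 13) {
  n <- sample.int(n_max, 1)
  tox_obs(sample.int(nrow(model$doses), n, replace = TRUE),
          stats::rbinom(n, 1, 0.3))
}

# A minimal constructed patient: constant pre-drug mPAP/CO, arbitrary
# post-start values, for alert and adjustment tests.
make_patient <- function(mpap, co = 5, start_day = 0, drug_start = 10,
                         drug_stop = NA, id = "T1") {
  n <- length(mpap)
  days <- data.frame(day = seq.int(start_day, length.out = n),
                     mpap = mpap, cardiac_output = co)
  patient_series(id, days, drug_start = drug_start, drug_stop = drug_stop,
                 baseline_window = c(start_day, drug_start - 1))
}
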