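# Bayesian continual reassessment method (CRM), one-parameter power model.
#
# Dose-toxicity model: p(tox | d) = d^alpha with standardized doses
# 0 < d_1 < ... < d_K < 1 (the "skeleton") and alpha ~ Gamma(shape, rate),
# default Gamma(1, 1) (a unit-rate exponential). All posterior quantities
# are computed by adaptive 1-D quadrature over alpha.

#' Construct a CRM power model
#'
#' Defines the dose grid, the skeleton of standardized doses, the Gamma prior
#' on the power parameter and the target toxicity probability for a Bayesian
#' continual reassessment method with toxicity model \eqn{p(tox|d) = d^\alpha}.
#'
#' The default skeleton is an illustrative four-level grid; it is not the
#' skeleton of any particular trial, and studies replaying their own data
#' should substitute the values from their statistical analysis plan. By
#' default the skeleton values are used directly as standardized doses
#' (standard CRM practice). With `calibrate_prior = TRUE` the standardized
#' doses are instead back-solved as \eqn{d = \exp(1 - 1/g)} so that the prior
#' mean toxicity at each dose equals the elicited guess \eqn{g} (only
#' meaningful for the Gamma(1,1) prior).
#'
#' @param dose_mg numeric vector of dose labels in mg, strictly increasing.
#' @param skeleton numeric vector of prior toxicity guesses in (0,1), strictly
#'   increasing, same length as `dose_mg`.
#' @param prior_shape,prior_rate shape and rate of the Gamma prior on alpha.
#' @param target target toxicity (dose-limiting event) probability in (0,1).
#' @param calibrate_prior logical; if TRUE, transform the skeleton so the
#'   prior mean toxicity equals the skeleton value at each dose.
#' @return An object of class `crm_model` with elements `doses` (a data frame
#'   with columns `index`, `label_mg`, `standardized_dose`), `prior_shape`,
#'   `prior_rate`, `target`.
#' @examples
#' m <- crm_model()
#' prior_mean_tox(m, 3)
#' @export
crm_model <- function(dose_mg = c(100, 200, 300, 400),
                      skeleton = c(0.05, 0.10, 0.20, 0.35),
                      prior_shape = 1, prior_rate = 1,
                      target = 0.20,
                      calibrate_prior = FALSE) {
  if (length(dose_mg) != length(skeleton))
    stop("'dose_mg' and 'skeleton' must have the same length")
  if (any(!is.finite(skeleton)) || any(skeleton <= 0) || any(skeleton >= 1))
    stop("skeleton values must lie strictly in (0, 1)")
  if (is.unsorted(skeleton, strictly = TRUE))
    stop("skeleton must be strictly increasing")
  if (is.unsorted(dose_mg, strictly = TRUE))
    stop("dose_mg must be strictly increasing")
  if (prior_shape <= 0 || prior_rate <= 0)
    stop("prior shape and rate must be positive")
  if (target <= 0 || target >= 1)
    stop("target must lie strictly in (0, 1)")
  d <- if (calibrate_prior) exp(1 - 1 / skeleton) else skeleton
  structure(list(
    doses = data.frame(index = seq_along(dose_mg),
                       label_mg = as.numeric(dose_mg),
                       standardized_dose = d),
    prior_shape = prior_shape,
    prior_rate = prior_rate,
    target = target
  ), class = "crm_model")
}

#' @export
print.crm_model <- function(x, ...) {
  cat(sprintf("CRM power model p(tox|d) = d^alpha, alpha ~ Gamma(%g, %g), target %g\n",
              x$prior_shape, x$prior_rate, x$target))
  print(x$doses, row.names = FALSE)
  invisible(x)
}

#' Toxicity observations for the CRM
#'
#' Validates per-patient dose assignments and binary dose-limiting toxicity
#' (DLT) outcomes against a model's dose grid. A DLT here is the trial's
#' tolerability event: drug discontinuation for more than 5 consecutive days
#' within the first 4 weeks due to a grade >= 2 adverse event.
#'
#' @param dose_index integer vector of assigned dose indices (1..K).
#' @param dlt integer/logical vector of 0/1 outcomes.
#' @param patient_id optional identifiers (default sequential).
#' @param model a `crm_model`; when supplied, indices are range-checked.
#' @return A data frame of class `tox_obs` with columns `patient_id`,
#'   `dose_index`, `dlt`, in enrolment order.
#' @export
tox_obs <- function(dose_index, dlt, patient_id = NULL, model = NULL) {
  dose_index <- as.integer(dose_index)
  dlt <- as.integer(dlt)
  if (length(dose_index) != length(dlt))
    stop("'dose_index' and 'dlt' must have equal length")
  if (any(is.na(dose_index)) || any(dose_index < 1L))
    stop("dose_index must be positive integers")
  if (!is.null(model) && any(dose_index > nrow(model$doses)))
    stop("dose_index outside the model's dose grid")
  if (any(!dlt %in% c(0L, 1L)))
    stop("dlt outcomes must be 0 or 1")
  if (is.null(patient_id)) patient_id <- seq_along(dose_index)
  out <- data.frame(patient_id = patient_id, dose_index = dose_index,
                    dlt = dlt, stringsAsFactors = FALSE)
  class(out) <- c("tox_obs", "data.frame")
  out
}

#' Prior mean toxicity probability at a dose
#'
#' Closed form: for alpha ~ Gamma(a, b), \eqn{E[d^\alpha] = (1 - \ln d / b)^{-a}},
#' the Gamma moment generating function evaluated at \eqn{\ln d}. For the
#' default Gamma(1,1) prior this is \eqn{1 / (1 - \ln d)}.
#'
#' @param model a `crm_model`.
#' @param dose_index dose index on the grid.
#' @return prior expected toxicity probability.
#' @export
prior_mean_tox <- function(model, dose_index) {
  stopifnot(inherits(model, "crm_model"))
  dose_index <- as.integer(dose_index)
  if (any(dose_index < 1L) || any(dose_index > nrow(model$doses)))
    stop("dose index out of range")
  d <- model$doses$standardized_dose[dose_index]
  (1 - log(d) / model$prior_rate)^(-model$prior_shape)
}

#' Log unnormalized posterior density of alpha
#'
#' Log of prior density times the Bernoulli power-model likelihood
#' \eqn{\prod_i d_i^{\alpha y_i} (1 - d_i^\alpha)^{1 - y_i}}.
#'
#' @param model a `crm_model`.
#' @param data a `tox_obs` data frame (possibly zero rows).
#' @param alpha positive scalar or vector of evaluation points.
#' @return log kernel values, same length as `alpha`.
#' @export
log_posterior_kernel <- function(model, data, alpha) {
  stopifnot(inherits(model, "crm_model"))
  if (any(alpha <= 0)) stop("alpha must be positive")
  lp <- stats::dgamma(alpha, shape = model$prior_shape,
                      rate = model$prior_rate, log = TRUE)
  if (!is.null(data) && nrow(data) > 0L) {
    d <- model$doses$standardized_dose[data$dose_index]
    y <- data$dlt
    # outer(): rows = observations, cols = alpha values
    la <- outer(log(d), alpha)              # alpha * log(d_i)
    ll <- la
    ndlt <- y != 1L
    ll[ndlt, ] <- log1p(-exp(la[ndlt, , drop = FALSE]))
    lp <- lp + colSums(ll)
  }
  lp
}

# Internal: normalizing constant and generic posterior expectations.
# Integrates exp(log kernel - shift) * g(alpha) over (0, upper) with
# stats::integrate; the shift (kernel maximum) guards against underflow
# once the likelihood contains many terms.
.crm_quadrature <- function(model, data, upper = 60, rel.tol = 1e-10) {
  opt <- stats::optimize(function(a) log_posterior_kernel(model, data, a),
                         interval = c(1e-8, upper), maximum = TRUE)
  shift <- opt$objective
  kern <- function(a) exp(log_posterior_kernel(model, data, a) - shift)
  intg <- function(g) {
    r <- stats::integrate(function(a) kern(a) * g(a), 0, upper,
                          rel.tol = rel.tol, abs.tol = 0,
                          subdivisions = 200L, stop.on.error = FALSE)
    if (r$message != "OK")
      stop("posterior quadrature did not converge: ", r$message)
    r$value
  }
  z <- intg(function(a) rep(1, length(a)))
  list(kern = kern, z = z, upper = upper,
       expect = function(g) intg(g) / z)
}

# Internal: posterior mean toxicity per dose, no median machinery.
# This is the fast path used inside trial simulation.
.posterior_mean_tox <- function(model, data) {
  q <- .crm_quadrature(model, data)
  d <- model$doses$standardized_dose
  vapply(d, function(di) q$expect(function(a) di^a), numeric(1))
}

# Internal: quantile of the posterior of alpha by bisection on the CDF.
.posterior_alpha_quantile <- function(q, p, tol = 1e-8) {
  cdf <- function(m) {
    r <- stats::integrate(q$kern, 0, m, rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 200L, stop.on.error = FALSE)
    r$value / q$z
  }
  lo <- 0; hi <- q$upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Posterior summaries of the CRM dose-toxicity curve
#'
#' Computes, by adaptive quadrature over alpha, the per-dose posterior mean
#' toxicity probabilities \eqn{E[d^\alpha | data]}, the per-dose posterior
#' medians (as \eqn{d^{m}} with \eqn{m} the posterior median of alpha, exact
#' because \eqn{d^\alpha} is monotone in alpha), the posterior mean and
#' quantiles of alpha, and the recommended dose (posterior mean closest to
#' target, ties to the lower dose).
#'
#' @param model a `crm_model`.
#' @param data a `tox_obs` data frame; may have zero rows (prior only).
#' @param alpha_probs probabilities at which alpha quantiles are reported.
#' @return Object of class `crm_posterior`: list with `mean_tox`,
#'   `median_tox`, `alpha_mean`, `alpha_quantiles`, `recommended_index`,
#'   `n_obs`, `n_dlt`, and the `model`.
#' @export
posterior_summaries <- function(model, data = NULL,
                                alpha_probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(model, "crm_model"))
  if (is.null(data)) data <- tox_obs(integer(0), integer(0))
  q <- .crm_quadrature(model, data)
  d <- model$doses$standardized_dose
  mean_tox <- vapply(d, function(di) q$expect(function(a) di^a), numeric(1))
  alpha_mean <- q$expect(identity)
  aq <- vapply(alpha_probs, function(p) .posterior_alpha_quantile(q, p),
               numeric(1))
  names(aq) <- as.character(alpha_probs)
  a_med <- if ("0.5" %in% names(aq)) aq[["0.5"]] else
    .posterior_alpha_quantile(q, 0.5)
  out <- structure(list(
    mean_tox = mean_tox,
    median_tox = d^a_med,
    alpha_mean = alpha_mean,
    alpha_quantiles = aq,
    n_obs = nrow(data),
    n_dlt = sum(data$dlt),
    model = model
  ), class = "crm_posterior")
  out$recommended_index <- recommend_dose(out, model)
  out
}

#' @export
print.crm_posterior <- function(x, digits = 3, ...) {
  cat(sprintf("CRM posterior after %d patients (%d DLTs)\n", x$n_obs, x$n_dlt))
  tab <- cbind(x$model$doses,
               mean_tox = round(x$mean_tox, digits),
               median_tox = round(x$median_tox, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("alpha: mean %.3f, median %.3f\n",
              x$alpha_mean, x$alpha_quantiles[["0.5"]]))
  cat(sprintf("recommended dose: level %d (%g mg)\n", x$recommended_index,
              x$model$doses$label_mg[x$recommended_index]))
  invisible(x)
}

#' Recommend the next dose
#'
#' Returns the dose whose posterior mean toxicity is closest to the target;
#' ties are broken to the lower dose. With `no_skip = TRUE`, escalation is
#' capped at one level above `previous_index`.
#'
#' @param summary a `crm_posterior` (or any list with a `mean_tox` vector).
#' @param model a `crm_model`.
#' @param previous_index dose index of the last treated patient, or NULL.
#' @param no_skip logical; forbid skipping untried levels during escalation.
#' @return recommended dose index.
#' @export
recommend_dose <- function(summary, model, previous_index = NULL,
                           no_skip = FALSE) {
  dev <- abs(summary$mean_tox - model$target)
  best <- which(dev <= min(dev) + 1e-12)[1]  # ties -> lower dose
  if (no_skip && !is.null(previous_index) && best > previous_index + 1L)
    best <- previous_index + 1L
  as.integer(best)
}

#' Replay a sequential CRM trial from recorded outcomes
#'
#' Recomputes the posterior (and the dose recommendation) after each
#' successive patient's 4-week outcome, exactly as a continuously updated
#' CRM would have seen the data. Deterministic; invariant to patient
#' relabeling.
#'
#' @param model a `crm_model`.
#' @param observations a `tox_obs` data frame in enrolment order.
#' @param no_skip passed to [recommend_dose()] at each step.
#' @return List of `crm_posterior` objects of length `nrow(observations)+1`;
#'   element 1 is the prior-only summary, element i+1 the posterior after
#'   patient i.
#' @export
replay_trial <- function(model, observations, no_skip = FALSE) {
  stopifnot(inherits(model, "crm_model"))
  n <- if (is.null(observations)) 0L else nrow(observations)
  out <- vector("list", n + 1L)
  out[[1L]] <- posterior_summaries(model, NULL)
  for (i in seq_len(n)) {
    s <- posterior_summaries(model, observations[seq_len(i), , drop = FALSE])
    prev <- observations$dose_index[i]
    s$recommended_index <- recommend_dose(s, model, previous_index = prev,
                                          no_skip = no_skip)
    out[[i + 1L]] <- s
  }
  out
}
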