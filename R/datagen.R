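#' Calibrate a lognormal event-time distribution to two quantile targets
#'
#' Finds the unique lognormal parameters \eqn{(\mu, \sigma)} such that
#' the event-time distribution places probability `p_cycle1` on the
#' first cycle and `p_window` on the whole follow-up window of `tau`
#' cycles:
#' \deqn{\Phi((\log 1 - \mu)/\sigma) = p_{c1}, \quad
#'       \Phi((\log \tau - \mu)/\sigma) = p_w.}
#' The closed-form solution is \eqn{\sigma = \log(\tau)/(z_w - z_1)} and
#' \eqn{\mu = -\sigma z_1} with \eqn{z_1 = \Phi^{-1}(p_{c1})},
#' \eqn{z_w = \Phi^{-1}(p_w)}.
#'
#' @param p_window Probability of an event within `tau` cycles (0, 1).
#' @param p_cycle1 Probability of an event within the first cycle; must
#'   be strictly smaller than `p_window`.
#' @param tau Follow-up window in cycles (> 1).
#' @return A list with elements `mu` and `sigma` (log-cycle scale).
#' @examples
#' calibrate_lognormal(0.30, 0.75 * 0.30, tau = 3)
#' @export
calibrate_lognormal <- function(p_window, p_cycle1, tau = 3) {
  stopifnot(tau > 1, p_window > 0, p_window < 1, p_cycle1 > 0)
  if (p_cycle1 >= p_window)
    stop("p_cycle1 must be strictly smaller than p_window")
  z1 <- stats::qnorm(p_cycle1)
  zw <- stats::qnorm(p_window)
  sigma <- log(tau) / (zw - z1)
  list(mu = -sigma * z1, sigma = sigma)
}

#' Bivariate lognormal event-time model for one dose combination
#'
#' Calibrates the marginal lognormal distributions of the latent
#' toxicity and activity times to the scenario's window probabilities
#' and per-cycle pattern: a fraction `tox_cycle1_fraction` (default
#' 0.75) of the window toxicity probability falls in cycle 1, while
#' activity is split equally across the `tau` cycles.  The two latent
#' log-times are coupled through a Gaussian copula with correlation
#' `rho` (default -0.5), which leaves both marginals untouched.
#'
#' Degenerate cells are handled so that every scenario matrix is
#' simulable: `p = 0` yields an infinite event time and `p = 1` is
#' capped just below 1 before calibration.
#'
#' @param p_tox,p_act Window event probabilities for the cell.
#' @param tau Follow-up window in cycles (default 3).
#' @param rho Latent-normal correlation in (-1, 1), default -0.5.
#' @param tox_cycle1_fraction Fraction of the window toxicity
#'   probability assigned to cycle 1 (default 0.75).
#' @return An object of class `event_time_model` with the marginal
#'   parameters (`mu_t`, `sigma_t`, `mu_a`, `sigma_a`; `NA` for a
#'   zero-probability margin) and `rho`.
#' @export
event_time_model <- function(p_tox, p_act, tau = 3, rho = -0.5,
                             tox_cycle1_fraction = 0.75) {
  stopifnot(abs(rho) < 1, tox_cycle1_fraction > 0, tox_cycle1_fraction < 1)
  cap <- function(p) min(p, 1 - 1e-9)
  mt <- if (p_tox > 0)
    calibrate_lognormal(cap(p_tox), tox_cycle1_fraction * cap(p_tox), tau)
  else list(mu = NA_real_, sigma = NA_real_)
  ma <- if (p_act > 0)
    calibrate_lognormal(cap(p_act), cap(p_act) / tau, tau)
  else list(mu = NA_real_, sigma = NA_real_)
  structure(list(mu_t = mt$mu, sigma_t = mt$sigma,
                 mu_a = ma$mu, sigma_a = ma$sigma,
                 rho = rho, tau = tau,
                 p_tox = p_tox, p_act = p_act),
            class = "event_time_model")
}

#' Sample correlated latent event times
#'
#' Draws `n` pairs \eqn{(t_T, t_A)} from the bivariate lognormal model:
#' correlated standard normals \eqn{(z_1, z_2)} with correlation `rho`
#' are mapped to \eqn{\exp(\mu + \sigma z)} per margin.  Margins with
#' zero event probability return `Inf`.  Uses the current R RNG state,
#' so results are reproducible under `set.seed()`.
#'
#' @param model An [event_time_model()].
#' @param n Number of pairs to draw.
#' @return A list with numeric vectors `t_tox` and `t_act` (cycles).
#' @export
sample_event_times <- function(model, n = 1) {
  stopifnot(inherits(model, "event_time_model"))
  z1 <- stats::rnorm(n)
  z2 <- model$rho * z1 + sqrt(1 - model$rho^2) * stats::rnorm(n)
  t_tox <- if (is.na(model$mu_t)) rep(Inf, n)
           else exp(model$mu_t + model$sigma_t * z1)
  t_act <- if (is.na(model$mu_a)) rep(Inf, n)
           else exp(model$mu_a + model$sigma_a * z2)
  list(t_tox = t_tox, t_act = t_act)
}

#' Simulate the latent outcomes of newly enrolled patients
#'
#' Composes [event_time_model()] and [sample_event_times()] for one dose
#' combination of a scenario and returns a [patient_records()] block for
#' a cohort entering at time `entry`.
#'
#' @param scenario A [scenario_spec()].
#' @param dose Length-2 integer vector `(i, j)`.
#' @param entry Entry time in cycles.
#' @param n_patients Cohort size.
#' @param first_id,cohort_id Ids assigned to the new patients.
#' @param tau,rho,tox_cycle1_fraction Passed to [event_time_model()].
#' @return A [patient_records()] table with `n_patients` rows.
#' @export
simulate_patients <- function(scenario, dose, entry, n_patients = 1,
                              first_id = 1L, cohort_id = 1L, tau = 3,
                              rho = -0.5, tox_cycle1_fraction = 0.75) {
  stopifnot(inherits(scenario, "scenario_spec"),
            length(dose) == 2,
            dose[1] >= 1, dose[1] <= scenario$grid$I,
            dose[2] >= 1, dose[2] <= scenario$grid$J)
  m <- event_time_model(scenario$p_tox[dose[1], dose[2]],
                        scenario$p_act[dose[1], dose[2]],
                        tau = tau, rho = rho,
                        tox_cycle1_fraction = tox_cycle1_fraction)
  tt <- sample_event_times(m, n_patients)
  patient_records(patient_id = seq.int(first_id, length.out = n_patients),
                  cohort_id = cohort_id, i = dose[1], j = dose[2],
                  entry = entry, t_tox = tt$t_tox, t_act = tt$t_act,
                  tau = tau)
}
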