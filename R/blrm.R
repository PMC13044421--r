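#' Single-agent logistic probability
#'
#' Two-parameter logistic model on the (scaled) actual dose of one
#' agent: \eqn{F(d) = \exp(\beta_0 + \beta_1 d)/(1 + \exp(\beta_0 +
#' \beta_1 d))}.
#'
#' @param d Dose (usually scaled by the agent's reference dose).
#' @param beta0,beta1 Intercept and slope.
#' @return Probability in (0, 1); vectorised.
#' @export
single_agent_prob <- function(d, beta0, beta1) {
  stats::plogis(beta0 + beta1 * d)
}

#' Combined odds of the dual-agent model
#'
#' Combines two single-agent event probabilities through the odds
#' formula with an interaction multiplier:
#' \deqn{\mathrm{odds}^0 = \frac{p_1}{1-p_1} + \frac{p_2}{1-p_2} +
#'       \frac{p_1 p_2}{(1-p_1)(1-p_2)}, \qquad
#'       \mathrm{odds} = \mathrm{odds}^0 e^{\eta d_1 d_2}.}
#' With \eqn{\eta = 0} and \eqn{p_2 = 0} this reduces exactly to the
#' single-agent odds.  A marginal probability of 1 yields infinite odds
#' (combined probability 1 downstream).
#'
#' @param p1,p2 Single-agent event probabilities in \[0, 1\].
#' @param eta Interaction coefficient.
#' @param d1_scaled,d2_scaled Scaled doses entering the interaction
#'   product.
#' @return The combined odds (possibly `Inf`).
#' @export
combined_odds <- function(p1, p2, eta = 0, d1_scaled = 0, d2_scaled = 0) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("probabilities must lie in [0, 1]")
  o1 <- p1 / (1 - p1)
  o2 <- p2 / (1 - p2)
  (o1 + o2 + o1 * o2) * exp(eta * d1_scaled * d2_scaled)
}

#' Combined event probability of the dual-agent model
#' @inheritParams combined_odds
#' @return `odds / (1 + odds)`, with probability 1 for infinite odds.
#' @export
combined_prob <- function(p1, p2, eta = 0, d1_scaled = 0, d2_scaled = 0) {
  o <- combined_odds(p1, p2, eta, d1_scaled, d2_scaled)
  ifelse(is.infinite(o), 1, o / (1 + o))
}

#' Prior for the Joint TITE-BLRM
#'
#' Independent normal priors on the 11 parameters: an intercept and
#' log-slope per agent per endpoint (8), one interaction coefficient per
#' endpoint (2), and the Gumbel association \eqn{\psi}.  Doses are
#' scaled by the reference doses `d_ref1` / `d_ref2` (by default the
#' highest planned dose of each agent) before entering the linear
#' predictors and the interaction product.
#'
#' @param intercept_mean,intercept_sd Prior on the four intercepts
#'   (default N(logit(0.15), 2^2)).
#' @param slope_mean,slope_sd Prior on the four log-slopes (default
#'   N(0, 1)).
#' @param eta_mean,eta_sd Prior on the two interaction coefficients
#'   (default N(0, 1)).
#' @param psi_mean,psi_sd Prior on psi (default N(0, 1)).
#' @param d_ref1,d_ref2 Reference doses (`NULL` = highest grid dose).
#' @return An object of class `blrm_prior`.
#' @export
blrm_prior <- function(intercept_mean = stats::qlogis(0.15),
                       intercept_sd = 2,
                       slope_mean = 0, slope_sd = 1,
                       eta_mean = 0, eta_sd = 1,
                       psi_mean = 0, psi_sd = 1,
                       d_ref1 = NULL, d_ref2 = NULL) {
  stopifnot(intercept_sd > 0, slope_sd > 0, eta_sd > 0, psi_sd > 0)
  mean <- c(rep(c(intercept_mean, slope_mean), 4), eta_mean, eta_mean,
            psi_mean)
  sd <- c(rep(c(intercept_sd, slope_sd), 4), eta_sd, eta_sd, psi_sd)
  structure(list(mean = mean, sd = sd, d_ref1 = d_ref1, d_ref2 = d_ref2),
            class = "blrm_prior")
}

blrm_scaled_doses <- function(grid, prior) {
  d_ref1 <- if (is.null(prior$d_ref1)) max(grid$w1) else prior$d_ref1
  d_ref2 <- if (is.null(prior$d_ref2)) max(grid$w2) else prior$d_ref2
  stopifnot(d_ref1 > 0, d_ref2 > 0)
  list(d1 = grid$w1 / d_ref1, d2 = grid$w2 / d_ref2)
}

#' Joint weighted log-likelihood of the BLRM
#'
#' Reference R implementation of the likelihood sampled by
#' [fit_blrm()]: per patient, the weighted combined probabilities
#' \eqn{w_T P_T(i, j)} and \eqn{w_A P_A(i, j)} (from [combined_prob()]
#' per endpoint) enter the Gumbel cell probability of the observed
#' \eqn{(y_A, y_T)} cell.
#'
#' @param theta Parameter vector of length 11:
#'   `(b0_w1t, log_b1_w1t, b0_w2t, log_b1_w2t, b0_w1a, log_b1_w1a,
#'   b0_w2a, log_b1_w2a, eta_t, eta_a, psi)`.
#' @param d1,d2 Scaled doses of each patient's combination.
#' @param w_t,w_a,y_t,y_a Weights and binary outcomes.
#' @return The log-likelihood.
#' @export
blrm_loglik <- function(theta, d1, d2, w_t, w_a, y_t, y_a) {
  stopifnot(length(theta) == 11)
  p_t <- w_t * combined_prob(single_agent_prob(d1, theta[1], exp(theta[2])),
                             single_agent_prob(d2, theta[3], exp(theta[4])),
                             theta[9], d1, d2)
  p_a <- w_a * combined_prob(single_agent_prob(d1, theta[5], exp(theta[6])),
                             single_agent_prob(d2, theta[7], exp(theta[8])),
                             theta[10], d1, d2)
  cells <- gumbel_cell_prob(p_a, p_t, theta[11], y_a, y_t)
  if (any(cells <= 0)) return(-Inf)
  sum(log(cells))
}

#' Fit the Joint TITE-BLRM
#'
#' Samples the 11-parameter posterior (per-agent logistic models per
#' endpoint, odds interaction coefficients, Gumbel association) with an
#' adaptive random-walk Metropolis sampler, and returns full-window
#' posterior probability draws of toxicity and activity for every dose
#' combination.
#'
#' @param obs Observation table from [observe()].
#' @param grid A [dose_grid()].
#' @param prior A [blrm_prior()].
#' @param mcmc An [mcmc_control()].
#' @param seed Optional integer seed.
#' @param fix_psi Optional value at which to fix psi.
#' @return A `posterior_summary`: matrices `pi_t`, `pi_a` (draws x dose
#'   cells), parameter `draws`, `accept_rate`.
#' @export
fit_blrm <- function(obs, grid, prior = blrm_prior(),
                     mcmc = mcmc_control(), seed = NULL, fix_psi = NULL) {
  stopifnot(inherits(grid, "dose_grid"), inherits(prior, "blrm_prior"))
  if (!is.null(seed)) set.seed(seed)
  sc <- blrm_scaled_doses(grid, prior)
  init <- prior$mean
  fixed <- rep(FALSE, 11)
  if (!is.null(fix_psi)) {
    init[11] <- fix_psi
    fixed[11] <- TRUE
  }
  ncell <- n_doses(grid)
  gtmp0 <- structure(list(I = grid$I, J = grid$J), class = "dose_grid")
  ij0 <- cell_ij(gtmp0, seq_len(ncell))
  cells <- cell_index(grid, obs$i, obs$j)
  fit <- mcmc_blrm_cpp(sc$d1[ij0[, "i"]], sc$d2[ij0[, "j"]],
                       as.integer(cells - 1L), obs$w_t, obs$w_a,
                       as.integer(obs$y_t), as.integer(obs$y_a),
                       prior$mean, prior$sd, init, fixed,
                       mcmc$burnin, mcmc$draws)
  d <- fit$draws
  pi_t <- pi_a <- matrix(NA_real_, nrow(d), ncell)
  for (k in seq_len(ncell)) {
    d1k <- sc$d1[ij0[k, "i"]]
    d2k <- sc$d2[ij0[k, "j"]]
    pi_t[, k] <- combined_prob(single_agent_prob(d1k, d[, 1], exp(d[, 2])),
                               single_agent_prob(d2k, d[, 3], exp(d[, 4])),
                               d[, 9], d1k, d2k)
    pi_a[, k] <- combined_prob(single_agent_prob(d1k, d[, 5], exp(d[, 6])),
                               single_agent_prob(d2k, d[, 7], exp(d[, 8])),
                               d[, 10], d1k, d2k)
  }
  structure(list(pi_t = pi_t, pi_a = pi_a, draws = d,
                 accept_rate = fit$accept_rate),
            class = "posterior_summary")
}

#' Joint TITE-BLRM design configuration
#'
#' @param prior A [blrm_prior()].
#' @param mcmc An [mcmc_control()].
#' @return An object of class `c("blrm_design", "dualtite_design")`.
#' @export
blrm_design <- function(prior = blrm_prior(), mcmc = mcmc_control()) {
  structure(list(prior = prior, mcmc = mcmc),
            class = c("blrm_design", "dualtite_design"))
}

#' @export
fit_design.blrm_design <- function(design, obs, grid, ...) {
  fit_blrm(obs, grid, prior = design$prior, mcmc = design$mcmc)
}
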