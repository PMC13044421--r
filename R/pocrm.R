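#' Default dose skeleton
#'
#' The working-model skeleton used by the partial order continual
#' reassessment method: prior guesses of the event probability attached
#' to the ordered positions of the flattened dose grid.  For up to ten
#' combinations the default is the reference skeleton
#' `(0.15, 0.19, 0.22, 0.26, 0.30, 0.34, 0.38, 0.42, 0.46, 0.50)`
#' truncated from the end (a 3 x 3 grid drops the final 0.50); larger
#' grids use an equally spaced sequence over the same range.
#'
#' @param n Number of dose combinations.
#' @return Strictly increasing numeric vector of length `n` in (0, 1).
#' @export
default_skeleton <- function(n) {
  ref <- c(0.15, 0.19, 0.22, 0.26, 0.30, 0.34, 0.38, 0.42, 0.46, 0.50)
  stopifnot(n >= 1)
  if (n <= length(ref)) ref[seq_len(n)]
  else seq(0.15, 0.50, length.out = n)
}

ordering_ranks <- function(grid, ordering) {
  r <- integer(n_doses(grid))
  r[ordering] <- seq_along(ordering)
  r
}

ordering_is_consistent <- function(grid, ordering) {
  r <- matrix(ordering_ranks(grid, ordering), grid$I, grid$J)
  ok <- TRUE
  if (grid$I > 1) ok <- ok && all(r[-grid$I, , drop = FALSE] <
                                  r[-1, , drop = FALSE])
  if (grid$J > 1) ok <- ok && all(r[, -grid$J, drop = FALSE] <
                                  r[, -1, drop = FALSE])
  ok
}

#' Default set of partial orderings for a dose grid
#'
#' Generates a small set of complete orderings of the `I x J` grid, each
#' consistent with within-agent monotonicity (the rank of \eqn{d_{ij}}
#' is below that of \eqn{d_{i+1,j}} and \eqn{d_{i,j+1}}): traversal by
#' columns of agent W2, by rows of agent W1, and four diagonal
#' traversals of the antidiagonals (within-diagonal order ascending,
#' descending, or alternating either way).  Duplicates are removed and a
#' uniform prior is placed on the set.  An ordering is encoded as the
#' vector of cell indices (column-major, `k = i + (j-1) I`) in
#' increasing rank order.
#'
#' @param I,J Grid dimensions.
#' @return An object of class `ordering_set`: list with `orderings` (a
#'   list of integer permutations) and `prior_probs`.
#' @export
default_orderings <- function(I, J) {
  stopifnot(I >= 1, J >= 1, I * J >= 1)
  idx <- function(i, j) (j - 1L) * I + i
  by_col <- as.integer(unlist(lapply(seq_len(J), function(j)
    idx(seq_len(I), j))))
  by_row <- as.integer(unlist(lapply(seq_len(I), function(i)
    idx(i, seq_len(J)))))
  diag_trav <- function(within) {
    out <- integer(0)
    for (s in 2:(I + J)) {
      is <- seq_len(I)[seq_len(I) >= s - J & seq_len(I) <= s - 1]
      is <- switch(within(s), asc = is, desc = rev(is))
      out <- c(out, idx(is, s - is))
    }
    as.integer(out)
  }
  cand <- list(
    by_col,
    by_row,
    diag_trav(function(s) "asc"),
    diag_trav(function(s) "desc"),
    diag_trav(function(s) if (s %% 2 == 0) "asc" else "desc"),
    diag_trav(function(s) if (s %% 2 == 0) "desc" else "asc"))
  cand <- unique(cand)
  grid <- list(I = I, J = J)
  keep <- vapply(cand, function(o)
    ordering_is_consistent(structure(grid, class = "dose_grid"), o), TRUE)
  orderings <- cand[keep]
  structure(list(orderings = orderings,
                 prior_probs = rep(1 / length(orderings),
                                   length(orderings))),
            class = "ordering_set")
}

#' Weighted one-parameter power-model log-likelihood
#'
#' The part-1 working model: \eqn{G(x, w, \alpha) = w x^{\exp(\alpha)}}
#' with Bernoulli contributions \eqn{G^y (1 - G)^{1-y}}.
#'
#' @param x Skeleton values of each patient's dose under the working
#'   model, in (0, 1).
#' @param y Binary outcomes.
#' @param w TITE weights in \[0, 1\].
#' @param alpha Power-model parameter (scalar).
#' @return The log-likelihood.
#' @export
power_loglik <- function(x, y, w, alpha) {
  stopifnot(length(x) == length(y), length(y) == length(w),
            all(x > 0 & x < 1), all(w >= 0 & w <= 1))
  if (any(w == 0 & y == 1))
    stop("impossible observation: event recorded with zero weight")
  if (!length(x)) return(0)
  g <- w * x^exp(alpha)
  ## term-wise to avoid 0 * Inf at extreme alpha (g -> 0 or 1)
  sum(log(g[y == 1])) + sum(log1p(-g[y == 0]))
}

## Log marginal likelihood of the power model under a N(mean, sd^2)
## prior on alpha, by mode-centred adaptive quadrature.
power_log_marginal <- function(x, y, w, prior_mean = 0, prior_sd = 1.34) {
  lp <- function(a) vapply(a, function(ai) {
    v <- power_loglik(x, y, w, ai) +
      stats::dnorm(ai, prior_mean, prior_sd, log = TRUE)
    if (is.finite(v)) v else -1e300  # keep optimize() off -Inf
  }, 0)
  opt <- stats::optimize(function(a) -lp(a),
                         interval = prior_mean + c(-12, 12) * prior_sd)
  l0 <- -opt$objective
  f <- function(a) exp(lp(a) - l0)
  int <- stats::integrate(f, lower = -Inf, upper = Inf,
                          stop.on.error = FALSE)
  log(int$value) + l0
}

#' Posterior probabilities of the partial orderings
#'
#' Part 1 of the Joint TITE-POCRM, applied to one endpoint at a time:
#' for each candidate ordering \eqn{m} the marginal likelihood
#' \eqn{\int L_m(\alpha) g(\alpha) d\alpha} of the weighted power model
#' is computed by adaptive quadrature and combined with the prior
#' ordering probabilities,
#' \eqn{p(m \mid \Omega) \propto p(m) \int L_m(\alpha) g(\alpha) d\alpha}.
#'
#' @param cells Integer vector of each patient's dose cell (column-major
#'   index into the grid).
#' @param y,w Binary outcomes and TITE weights for the endpoint.
#' @param orderings An `ordering_set` (e.g. [default_orderings()]).
#' @param skeleton Skeleton vector, length `I * J`.
#' @param prior_mean,prior_sd Normal prior on the power parameter
#'   \eqn{\alpha} (default N(0, 1.34^2)).
#' @return Numeric vector of posterior ordering probabilities (sums
#'   to 1).
#' @export
ordering_posteriors <- function(cells, y, w, orderings, skeleton,
                                prior_mean = 0, prior_sd = 1.34) {
  stopifnot(inherits(orderings, "ordering_set"))
  M <- length(orderings$orderings)
  if (!length(cells)) return(orderings$prior_probs)
  logml <- vapply(seq_len(M), function(m) {
    ranks <- integer(length(skeleton))
    ranks[orderings$orderings[[m]]] <- seq_along(skeleton)
    x <- skeleton[ranks[cells]]
    power_log_marginal(x, y, w, prior_mean, prior_sd)
  }, 0)
  lp <- log(orderings$prior_probs) + logml
  if (all(!is.finite(lp))) stop("all ordering marginal likelihoods are zero")
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Select the ordering with highest posterior probability
#'
#' Ties are broken deterministically in favour of the lowest index.
#'
#' @param posteriors Normalised posterior ordering probabilities.
#' @return The index of the selected ordering.
#' @export
select_ordering <- function(posteriors) which.max(posteriors)

#' Gumbel-model cell probabilities for bivariate binary outcomes
#'
#' Probability of the outcome cell \eqn{(y_A = a, y_T = b)} for
#' Bernoulli marginals \eqn{(p_A, p_T)} coupled by the Gumbel model with
#' association parameter \eqn{\psi}:
#' \deqn{p_A^a (1-p_A)^{1-a} p_T^b (1-p_T)^{1-b} +
#'   (-1)^{a+b} p_A (1-p_A) p_T (1-p_T)
#'   \frac{e^\psi - 1}{e^\psi + 1}.}
#' The four cells always sum to 1; each is floored at 0 for likelihood
#' stability.  \eqn{\psi = 0} gives independence.
#'
#' @param p_a,p_t Marginal probabilities in \[0, 1\] (vectorised).
#' @param psi Association parameter.
#' @param a,b Binary indicators for activity and toxicity.
#' @return Cell probabilities.
#' @export
gumbel_cell_prob <- function(p_a, p_t, psi, a, b) {
  m_a <- ifelse(a == 1, p_a, 1 - p_a)
  m_t <- ifelse(b == 1, p_t, 1 - p_t)
  sgn <- (-1)^(a + b)
  pmax(m_a * m_t +
         sgn * p_a * (1 - p_a) * p_t * (1 - p_t) * tanh(psi / 2), 0)
}

#' Joint weighted log-likelihood of the POCRM part-2 model
#'
#' Reference R implementation of the likelihood sampled by
#' [fit_joint_logistic()]: per patient, the weighted marginals
#' \eqn{w_T F(x_T; \beta^{(T)})} and \eqn{w_A F(x_A; \beta^{(A)})} enter
#' the Gumbel cell probability of the observed \eqn{(y_A, y_T)} cell.
#'
#' @param theta Parameter vector
#'   `(b0_t, log_b1_t, b0_a, log_b1_a, psi)`.
#' @param x_t,x_a Skeleton values per patient under the selected
#'   toxicity/activity orderings.
#' @param w_t,w_a,y_t,y_a Weights and binary outcomes per patient.
#' @return The log-likelihood.
#' @export
pocrm_joint_loglik <- function(theta, x_t, x_a, w_t, w_a, y_t, y_a) {
  p_t <- w_t * stats::plogis(theta[1] + exp(theta[2]) * x_t)
  p_a <- w_a * stats::plogis(theta[3] + exp(theta[4]) * x_a)
  cells <- gumbel_cell_prob(p_a, p_t, theta[5], y_a, y_t)
  if (any(cells <= 0)) return(-Inf)
  sum(log(cells))
}

#' Calibrate the logistic prior means to a skeleton
#'
#' Least-squares fit of \eqn{\mathrm{logit}(x_k) \approx c_1 + e^{c_2} x_k}
#' over the skeleton points, so that the prior mean dose-response curve
#' of the two-parameter logistic model passes close to the skeleton.
#'
#' @param skeleton Skeleton vector (length >= 2).
#' @return List with `c1` (intercept prior mean) and `c2` (log-slope
#'   prior mean).
#' @export
calibrate_logistic_prior <- function(skeleton) {
  if (length(skeleton) < 2) stop("need at least two skeleton points")
  fit <- stats::lm(stats::qlogis(skeleton) ~ skeleton)
  b <- unname(stats::coef(fit))
  if (b[2] <= 0) stop("skeleton implies a non-increasing logistic curve")
  list(c1 = b[1], c2 = log(b[2]))
}

#' Prior for the joint two-parameter logistic model
#'
#' Bivariate normal prior on \eqn{(\beta_0, \log \beta_1)} per endpoint
#' (diagonal covariance) plus a normal prior on the Gumbel association
#' \eqn{\psi}.  When `c1`/`c2` are `NULL` they are filled in per
#' endpoint by [calibrate_logistic_prior()] at fit time.
#'
#' @param c1,c2 Prior means of the intercept and log-slope (or `NULL`).
#' @param v1,v2 Prior variances (defaults 1.0 and 0.5).
#' @param psi_mean,psi_sd Normal prior on psi (default N(0, 1)).
#' @return An object of class `logistic_prior`.
#' @export
logistic_prior <- function(c1 = NULL, c2 = NULL, v1 = 1.0, v2 = 0.5,
                           psi_mean = 0, psi_sd = 1) {
  stopifnot(v1 > 0, v2 > 0, psi_sd > 0)
  structure(list(c1 = c1, c2 = c2, v1 = v1, v2 = v2,
                 psi_mean = psi_mean, psi_sd = psi_sd),
            class = "logistic_prior")
}

#' MCMC control settings
#'
#' @param burnin Burn-in sweeps (default 2000).
#' @param draws Retained draws (default 4000).
#' @return A list.
#' @export
mcmc_control <- function(burnin = 2000, draws = 4000) {
  stopifnot(burnin >= 0, draws >= 1)
  list(burnin = as.integer(burnin), draws = as.integer(draws))
}

#' Fit the joint two-parameter logistic model (POCRM part 2)
#'
#' Samples \eqn{(\beta_0^{(T)}, \log\beta_1^{(T)}, \beta_0^{(A)},
#' \log\beta_1^{(A)}, \psi)} from the posterior whose likelihood couples
#' the weighted logistic marginals through the Gumbel model
#' ([pocrm_joint_loglik()]), using an adaptive random-walk Metropolis
#' sampler.  The log-slope parameterisation enforces \eqn{\beta_1 > 0},
#' so every retained draw is monotone across the selected ordering.
#'
#' @param obs Observation table from [observe()].
#' @param grid A [dose_grid()].
#' @param ordering_t,ordering_a Selected orderings (cell-index
#'   permutations) for toxicity and activity.
#' @param skeleton_t,skeleton_a Skeletons per endpoint.
#' @param prior A [logistic_prior()] used for both endpoints.
#' @param mcmc An [mcmc_control()].
#' @param seed Optional integer seed (`set.seed` applied when given).
#' @param fix_psi Optional value at which to fix the association
#'   parameter (e.g. 0 for independent endpoints).
#' @return A `posterior_summary`: list with matrices `pi_t` and `pi_a`
#'   (draws x dose cells, full-window probabilities at weight 1),
#'   `draws` of the parameters, and `accept_rate`.
#' @export
fit_joint_logistic <- function(obs, grid, ordering_t, ordering_a,
                               skeleton_t = default_skeleton(n_doses(grid)),
                               skeleton_a = skeleton_t,
                               prior = logistic_prior(),
                               mcmc = mcmc_control(), seed = NULL,
                               fix_psi = NULL) {
  stopifnot(inherits(grid, "dose_grid"), inherits(prior, "logistic_prior"))
  if (!is.null(seed)) set.seed(seed)
  cal_t <- calibrate_logistic_prior(skeleton_t)
  cal_a <- calibrate_logistic_prior(skeleton_a)
  c1t <- if (is.null(prior$c1)) cal_t$c1 else prior$c1
  c2t <- if (is.null(prior$c2)) cal_t$c2 else prior$c2
  c1a <- if (is.null(prior$c1)) cal_a$c1 else prior$c1
  c2a <- if (is.null(prior$c2)) cal_a$c2 else prior$c2
  prior_mean <- c(c1t, c2t, c1a, c2a, prior$psi_mean)
  prior_sd <- c(sqrt(prior$v1), sqrt(prior$v2),
                sqrt(prior$v1), sqrt(prior$v2), prior$psi_sd)
  init <- prior_mean
  fixed <- rep(FALSE, 5)
  if (!is.null(fix_psi)) {
    init[5] <- fix_psi
    fixed[5] <- TRUE
  }
  rank_t <- integer(n_doses(grid)); rank_t[ordering_t] <- seq_along(ordering_t)
  rank_a <- integer(n_doses(grid)); rank_a[ordering_a] <- seq_along(ordering_a)
  cells <- cell_index(grid, obs$i, obs$j)
  fit <- mcmc_pocrm_cpp(skeleton_t[rank_t], skeleton_a[rank_a],
                        as.integer(cells - 1L), obs$w_t, obs$w_a,
                        as.integer(obs$y_t), as.integer(obs$y_a),
                        prior_mean, prior_sd, init, fixed,
                        mcmc$burnin, mcmc$draws)
  d <- fit$draws
  pi_t <- stats::plogis(d[, 1] + exp(d[, 2]) %o% skeleton_t[rank_t])
  pi_a <- stats::plogis(d[, 3] + exp(d[, 4]) %o% skeleton_a[rank_a])
  structure(list(pi_t = pi_t, pi_a = pi_a, draws = d,
                 accept_rate = fit$accept_rate,
                 ordering_t = ordering_t, ordering_a = ordering_a),
            class = "posterior_summary")
}

#' Joint TITE-POCRM design configuration
#'
#' @param skeleton_t,skeleton_a Skeletons for toxicity and activity
#'   (`NULL` = [default_skeleton()] for the grid at run time; the
#'   activity skeleton defaults to the toxicity skeleton).
#' @param orderings_t,orderings_a Ordering sets (`NULL` =
#'   [default_orderings()] for the grid).
#' @param power_prior_mean,power_prior_sd Normal prior on the part-1
#'   power parameter.
#' @param prior A [logistic_prior()] for part 2.
#' @param mcmc An [mcmc_control()].
#' @return An object of class `c("pocrm_design", "dualtite_design")`.
#' @export
pocrm_design <- function(skeleton_t = NULL, skeleton_a = NULL,
                         orderings_t = NULL, orderings_a = NULL,
                         power_prior_mean = 0, power_prior_sd = 1.34,
                         prior = logistic_prior(),
                         mcmc = mcmc_control()) {
  structure(list(skeleton_t = skeleton_t, skeleton_a = skeleton_a,
                 orderings_t = orderings_t, orderings_a = orderings_a,
                 power_prior_mean = power_prior_mean,
                 power_prior_sd = power_prior_sd,
                 prior = prior, mcmc = mcmc),
            class = c("pocrm_design", "dualtite_design"))
}

## Fit dispatcher used by the trial loop: returns a posterior_summary
## with full-window pi_t / pi_a draws for every grid cell.
fit_design <- function(design, obs, grid, ...) UseMethod("fit_design")

#' @export
fit_design.pocrm_design <- function(design, obs, grid, ...) {
  n <- n_doses(grid)
  skel_t <- if (is.null(design$skeleton_t)) default_skeleton(n)
            else design$skeleton_t
  skel_a <- if (is.null(design$skeleton_a)) skel_t else design$skeleton_a
  ord_t <- if (is.null(design$orderings_t)) default_orderings(grid$I, grid$J)
           else design$orderings_t
  ord_a <- if (is.null(design$orderings_a)) ord_t else design$orderings_a
  cells <- cell_index(grid, obs$i, obs$j)
  post_t <- ordering_posteriors(cells, obs$y_t, obs$w_t, ord_t, skel_t,
                                design$power_prior_mean,
                                design$power_prior_sd)
  post_a <- ordering_posteriors(cells, obs$y_a, obs$w_a, ord_a, skel_a,
                                design$power_prior_mean,
                                design$power_prior_sd)
  m_t <- select_ordering(post_t)
  m_a <- select_ordering(post_a)
  fit_joint_logistic(obs, grid,
                     ordering_t = ord_t$orderings[[m_t]],
                     ordering_a = ord_a$orderings[[m_a]],
                     skeleton_t = skel_t, skeleton_a = skel_a,
                     prior = design$prior, mcmc = design$mcmc)
}
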