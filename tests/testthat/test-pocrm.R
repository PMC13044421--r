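test_that("default ordering sets are monotone-consistent and include the reference traversal", {
  for (dims in list(c(2, 5), c(3, 3), c(2, 2))) {
    os <- default_orderings(dims[1], dims[2])
    expect_gt(length(os$orderings), 1)
    expect_equal(sum(os$prior_probs), 1)
    I <- dims[1]; J <- dims[2]
    for (o in os$orderings) {
      expect_setequal(o, seq_len(I * J))
      r <- matrix(0L, I, J)
      r[o] <- seq_len(I * J)
      expect_true(all(r[-I, , drop = FALSE] < r[-1, , drop = FALSE]))
      expect_true(all(r[, -J, drop = FALSE] < r[, -1, drop = FALSE]))
    }
  }
  # the worked 2x5 traversal d11,d21,d12,d22,...,d15,d25 (column-major 1..10)
  os <- default_orderings(2, 5)
  expect_true(any(sapply(os$orderings, identical, y = 1:10)))
  # degenerate one-dimensional grid: single full ordering
  expect_length(default_orderings(1, 5)$orderings, 1)
})

test_that("power-model log-likelihood matches a brute-force product", {
  expect_equal(power_loglik(numeric(0), integer(0), numeric(0), 0.3), 0)
  expect_equal(power_loglik(0.15, 0, 1, 0), log(0.85))
  expect_error(power_loglik(0.3, 1, 0, 0), "zero weight")
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    x <- runif(n, 0.05, 0.6); y <- rbinom(n, 1, 0.3)
    w <- runif(n, 0.1, 1); a <- rnorm(1)
    g <- w * x^exp(a)
    expect_equal(power_loglik(x, y, w, a),
                 log(prod(ifelse(y == 1, g, 1 - g))))
  }
  # extreme alpha values stay finite or -Inf, never NaN
  expect_false(is.nan(power_loglik(c(0.2, 0.4), c(1, 0), c(1, 1), -15)))
  expect_false(is.nan(power_loglik(c(0.2, 0.4), c(1, 0), c(1, 1), 15)))
})

test_that("ordering posteriors agree with a Monte-Carlo integration oracle", {
  g <- grid_2x5()
  os <- default_orderings(2, 5)
  skel <- default_skeleton(10)
  # no data: the prior is returned; single ordering: probability 1
  expect_equal(ordering_posteriors(integer(0), integer(0), numeric(0),
                                   os, skel), os$prior_probs)
  one <- structure(list(orderings = os$orderings[1], prior_probs = 1),
                   class = "ordering_set")
  expect_equal(ordering_posteriors(c(1, 4), c(0, 1), c(1, 1), one, skel), 1)
  # two orderings ranking one cell near the bottom vs near the top
  two <- structure(list(orderings = list(os$orderings[[1]],
                                         os$orderings[[2]]),
                        prior_probs = c(0.5, 0.5)),
                   class = "ordering_set")
  cells <- c(2, 2, 2, 3, 3)       # d21 x3, d12 x2
  y <- c(1, 1, 0, 0, 0)
  w <- c(1, 1, 1, 0.8, 0.5)
  post <- ordering_posteriors(cells, y, w, two, skel)
  expect_equal(sum(post), 1)
  # oracle: marginal likelihood by Monte-Carlo over the alpha prior
  set.seed(71)
  draws <- rnorm(2e5, 0, 1.34)
  ml <- sapply(two$orderings, function(o) {
    rk <- integer(10); rk[o] <- 1:10
    x <- skel[rk[cells]]
    lik <- sapply(draws, function(a) exp(power_loglik(x, y, w, a)))
    c(mean(lik), sd(lik) / sqrt(length(lik)))
  })
  mc_post <- ml[1, ] / sum(ml[1, ])
  mc_se <- mc_post * sqrt(sum((ml[2, ] / ml[1, ])^2))
  expect_lt(abs(post[1] - mc_post[1]), 3 * mc_se[1])
  # invariance to relabeling of the orderings
  swapped <- structure(list(orderings = rev(two$orderings),
                            prior_probs = c(0.5, 0.5)),
                       class = "ordering_set")
  expect_equal(rev(ordering_posteriors(cells, y, w, swapped, skel)), post,
               tolerance = 1e-8)
})

test_that("ordering selection breaks ties at the lowest index", {
  expect_equal(select_ordering(c(0.2, 0.8)), 2L)
  expect_equal(select_ordering(c(0.5, 0.5)), 1L)
  expect_equal(select_ordering(rep(0.25, 4)), 1L)
})

test_that("Gumbel cell probabilities behave as a proper bivariate binary law", {
  # independence at psi = 0
  for (a in 0:1) for (b in 0:1)
    expect_equal(gumbel_cell_prob(0.5, 0.5, 0, a, b), 0.25)
  # cells sum to one for random parameters
  set.seed(41)
  for (rep in 1:50) {
    pa <- runif(1); pt <- runif(1); psi <- rnorm(1, 0, 2)
    tot <- sum(sapply(0:1, function(a) sapply(0:1, function(b)
      gumbel_cell_prob(pa, pt, psi, a, b))))
    expect_equal(tot, 1, tolerance = 1e-12)
    # R and C++ implementations agree
    expect_equal(gumbel_cell_prob(pa, pt, psi, 1, 0),
                 gumbel_cell_cpp(pa, pt, psi, 1L, 0L))
  }
  # limiting association: 0.25 + 0.0625 * tanh(psi/2) -> 0.3125
  expect_equal(gumbel_cell_prob(0.5, 0.5, 50, 1, 1), 0.3125,
               tolerance = 1e-6)
})

test_that("logistic prior calibration is the least-squares fit through the skeleton", {
  skel <- default_skeleton(10)
  cal <- calibrate_logistic_prior(skel)
  # closed-form simple-regression oracle
  slope <- cov(skel, qlogis(skel)) / var(skel)
  intercept <- mean(qlogis(skel)) - slope * mean(skel)
  expect_equal(cal$c1, intercept)
  expect_equal(cal$c2, log(slope))
  # prior mean curve tracks the skeleton closely
  fitted <- plogis(cal$c1 + exp(cal$c2) * skel)
  expect_lt(max(abs(fitted - skel)), 0.05)
  # symmetric skeleton: the line passes through (0.5, 0)
  sym <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  cs <- calibrate_logistic_prior(sym)
  expect_equal(cs$c1, -exp(cs$c2) * 0.5, tolerance = 1e-8)
  expect_error(calibrate_logistic_prior(0.3), "two skeleton")
})

test_that("joint logistic likelihood matches its C++ mirror and factorises at psi = 0", {
  skel <- default_skeleton(10)
  set.seed(55)
  for (rep in 1:10) {
    d <- random_obs(15, 10, seed = 100 + rep)
    th <- c(rnorm(2), rnorm(2), rnorm(1))
    r_ll <- pocrm_joint_loglik(th, skel[d$cell], skel[d$cell],
                               d$w_t, d$w_a, d$y_t, d$y_a)
    cpp_ll <- pocrm_loglik_cpp(th, skel, skel, as.integer(d$cell - 1L),
                               d$w_t, d$w_a,
                               as.integer(d$y_t), as.integer(d$y_a))
    expect_equal(r_ll, cpp_ll, tolerance = 1e-10)
  }
  # psi = 0 and full weights: product of two independent Bernoulli models
  d <- random_obs(30, 10, seed = 7)
  d$w_t <- 1; d$w_a <- 1
  th <- c(-1, 0.5, -0.5, 0.2, 0)
  pt <- plogis(th[1] + exp(th[2]) * skel[d$cell])
  pa <- plogis(th[3] + exp(th[4]) * skel[d$cell])
  indep <- sum(dbinom(d$y_t, 1, pt, log = TRUE)) +
    sum(dbinom(d$y_a, 1, pa, log = TRUE))
  expect_equal(pocrm_joint_loglik(th, skel[d$cell], skel[d$cell],
                                  d$w_t, d$w_a, d$y_t, d$y_a), indep)
})

test_that("the joint logistic fit is seeded, prior-centred and recovers a rate", {
  g <- grid_2x5()
  # zero patients: posterior ~ prior, centred near the skeleton
  none <- complete_obs(integer(0), integer(0), integer(0), integer(0))
  f1 <- fit_joint_logistic(none, g, 1:10, 1:10, seed = 3)
  f2 <- fit_joint_logistic(none, g, 1:10, 1:10, seed = 3)
  expect_identical(f1$draws, f2$draws)
  skel <- default_skeleton(10)
  med <- apply(f1$pi_t, 2, median)
  expect_lt(max(abs(med - skel)), 0.1)
  # monotone across the ordering for every retained draw (ties only at
  # floating-point resolution when a draw's slope underflows)
  expect_true(all(apply(f1$pi_t, 1, function(r) all(diff(r) >= 0))))
  # 60 patients on one cell with a 30% toxicity rate
  obs <- complete_obs(rep(2, 60), rep(2, 60),
                      rep(c(1, 0), c(18, 42)), rep(c(1, 0), c(24, 36)))
  f3 <- fit_joint_logistic(obs, g, 1:10, 1:10, seed = 9)
  m <- mean(f3$pi_t[, 4])   # cell d22 = index 4
  expect_gt(m, 0.2); expect_lt(m, 0.4)
})
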