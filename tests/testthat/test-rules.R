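test_that("the dose-skipping rule yields the printed allowable sets", {
  g <- grid_2x5()
  allow <- allowable_doses(cbind(2, 2), g)   # explored = d22
  ij <- cbind(((allow - 1) %% 2) + 1, ((allow - 1) %/% 2) + 1)
  lab <- paste0("d", ij[, 1], ij[, 2])
  expect_setequal(lab, c("d11", "d21", "d12", "d22", "d13", "d23"))
  g3 <- grid_3x3()
  allow3 <- allowable_doses(cbind(1, 1), g3)
  ij3 <- cbind(((allow3 - 1) %% 3) + 1, ((allow3 - 1) %/% 3) + 1)
  expect_setequal(paste0("d", ij3[, 1], ij3[, 2]), c("d11", "d12", "d21"))
  expect_length(allowable_doses(integer(0), g), 0)
})

test_that("beta-binomial exceedance probabilities match closed forms", {
  # Beta(4, 1): P(p > 0.3) = 1 - 0.3^4
  expect_equal(posterior_prob_exceed(3, 3, 0.3), 1 - 0.3^4)
  # uniform prior
  expect_equal(posterior_prob_exceed(0, 0, 0.3), 0.7)
  # Beta(6, 5) via the binomial-tail identity
  expect_equal(posterior_prob_exceed(5, 9, 0.3),
               pbinom(5, 10, 0.3))
  expect_equal(posterior_prob_exceed(5, 9, 0.3), 0.9527, tolerance = 1e-4)
})

test_that("hard safety reproduces the printed count boundaries and monotone exclusion", {
  g <- grid_2x5()
  counts <- function(y, n, i = 1, j = 2) data.frame(i = i, j = j,
                                                    y = y, n = n)
  # minimal triggering counts at n = 3, 6, 9 are exactly 3, 4, 5
  for (n in c(3, 6, 9)) {
    y_min <- min(which(sapply(0:n, function(y)
      posterior_prob_exceed(y, n, 0.3) > 0.95))) - 1
    expect_equal(y_min, c(`3` = 3, `6` = 4, `9` = 5)[[as.character(n)]])
  }
  expect_length(hard_safety_exclusions(counts(2, 3), g), 0)
  expect_length(hard_safety_exclusions(counts(3, 6), g), 0)
  expect_length(hard_safety_exclusions(counts(4, 9), g), 0)
  # 3/3 at d12 excludes every cell weakly higher in both agents
  ex <- hard_safety_exclusions(counts(3, 3), g)
  ij <- cbind(((ex - 1) %% 2) + 1, ((ex - 1) %/% 2) + 1)
  expect_setequal(paste0("d", ij[, 1], ij[, 2]),
                  c("d12", "d13", "d14", "d15",
                    "d22", "d23", "d24", "d25"))
  expect_gt(length(hard_safety_exclusions(counts(4, 6), g)), 0)
})

test_that("admissibility thresholds act on posterior draw fractions", {
  post <- function(pt, pa) {
    structure(list(pi_t = matrix(pt, ncol = 1),
                   pi_a = matrix(pa, ncol = 1)),
              class = "posterior_summary")
  }
  adm <- admissibility_params()
  expect_equal(admissible_set(post(rep(0.1, 100), rep(0.5, 100)), adm), 1L)
  expect_length(admissible_set(post(rep(0.1, 100), rep(0.05, 100)), adm), 0)
  # borderline: exactly half the draws safe clears q_t = 0.2
  mixed <- post(rep(c(0.1, 0.6), 50), rep(0.5, 100))
  expect_equal(admissible_set(mixed, adm), 1L)
})

test_that("dose selection maximises posterior mean utility with lexicographic ties", {
  g <- grid_2x5()
  mk_post <- function(pa4, pa6) {
    pi_t <- matrix(0.1, 100, 10)
    pi_a <- matrix(0.05, 100, 10)
    pi_a[, 4] <- pa4; pi_a[, 6] <- pa6
    structure(list(pi_t = pi_t, pi_a = pi_a),
              class = "posterior_summary")
  }
  expect_equal(select_dose(mk_post(0.4, 0.5), c(4L, 6L), g), c(2L, 3L))
  expect_equal(select_dose(mk_post(0.5, 0.4), c(4L, 6L), g), c(2L, 2L))
  # tie: cell 4 = (2,2), cell 6 = (2,3) -> lowest (i, j) wins
  expect_equal(select_dose(mk_post(0.5, 0.5), c(4L, 6L), g), c(2L, 2L))
  expect_null(select_dose(mk_post(0.4, 0.5), integer(0), g))
})

test_that("trials are reproducible and respect enrolment limits", {
  s <- load_scenarios("T1.A1")[[1]]
  cfg <- trial_config()
  r1 <- run_trial(boin12_design(), s, cfg, seed = 11)
  r2 <- run_trial(boin12_design(), s, cfg, seed = 11)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$recommendation, r2$recommendation)
  expect_identical(r1$stop_reason, r2$stop_reason)
  expect_lte(r1$n_patients, cfg$n_max)
  # model-based arm, fast settings: determinism and limits
  des <- pocrm_design(mcmc = mcmc_control(200, 400))
  p1 <- run_trial(des, s, cfg, seed = 4)
  p2 <- run_trial(des, s, cfg, seed = 4)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$recommendation, p2$recommendation)
  expect_lte(p1$n_patients, cfg$n_max)
  expect_equal(sum(p1$assignments), p1$n_patients)
})

test_that("extreme scenarios drive the expected stopping behaviour", {
  g <- grid_2x5()
  hot <- scenario_spec(g, matrix(0.95, 2, 5), matrix(0.5, 2, 5), "hot")
  cold <- scenario_spec(g, matrix(0.03, 2, 5), matrix(0.6, 2, 5), "cold")
  safety_reasons <- c("hard_safety_all", "lowest_unsafe", "no_admissible")
  res_hot <- lapply(1:25, function(k) run_trial(boin12_design(), hot,
                                                trial_config(), seed = k))
  expect_true(all(sapply(res_hot, function(r)
    r$stop_reason %in% safety_reasons)))
  expect_true(all(sapply(res_hot, function(r)
    is.null(r$recommendation))))
  expect_lt(mean(sapply(res_hot, `[[`, "n_patients")), 20)
  res_cold <- lapply(1:25, function(k) run_trial(boin12_design(), cold,
                                                 trial_config(), seed = k))
  expect_gt(mean(sapply(res_cold, function(r)
    !is.null(r$recommendation))), 0.9)
  # a none-recommendation occurs exactly for the none stop reasons
  for (r in c(res_hot, res_cold)) {
    expect_equal(is.null(r$recommendation),
                 r$stop_reason %in% safety_reasons)
  }
})

test_that("trial results export to JSON and CSV", {
  s <- load_scenarios("T1.A1")[[1]]
  r <- run_trial(boin12_design(), s, trial_config(), seed = 2)
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  export_trial_result(r, jf, cf)
  back <- jsonlite::fromJSON(jf)
  expect_equal(back$stop_reason, r$stop_reason)
  expect_equal(back$n_patients, r$n_patients)
  expect_equal(nrow(read.csv(cf)), r$n_patients)
})
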