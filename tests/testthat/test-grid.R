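test_that("utility matches the trade-off definition in both penalty forms", {
  expect_equal(compute_utility(0.20, 0.10), 0.167)
  expect_equal(compute_utility(0, 0), 0)
  # penalty indicator is strict: no penalty at exactly the target
  expect_equal(compute_utility(0.30, 0.30), 0.30 - 0.33 * 0.30)
  fixed <- utility_params(penalty_form = "fixed")
  scaled <- utility_params(penalty_form = "scaled")
  # forms agree at or below the target, differ strictly above
  expect_equal(compute_utility(0.4, 0.25, fixed),
               compute_utility(0.4, 0.25, scaled))
  expect_equal(compute_utility(0.4, 0.5, fixed), 0.4 - 0.165 - 1.09)
  expect_equal(compute_utility(0.4, 0.5, scaled), 0.4 - 0.165 - 1.09 * 0.5)
  expect_error(compute_utility(1.2, 0.1), "0, 1")
})

test_that("utility is monotone: decreasing in pi_T, increasing in pi_A", {
  set.seed(11)
  p <- utility_params()
  for (rep in 1:50) {
    pa <- runif(1); pt <- sort(runif(2))
    expect_gt(compute_utility(pa, pt[1], p), compute_utility(pa, pt[2], p))
    pas <- sort(runif(2)); pt1 <- runif(1)
    expect_lt(compute_utility(pas[1], pt1, p),
              compute_utility(pas[2], pt1, p))
  }
})

test_that("weights recovered by linear elimination reproduce the printed 3x3 utilities", {
  sc <- load_scenarios(paste0("S", 1:6))
  s1 <- sc$S1; s6 <- sc$S6
  no_pen <- data.frame(pi_a = c(s1$p_act[1, 1], s1$p_act[1, 2]),
                       pi_t = c(s1$p_tox[1, 1], s1$p_tox[1, 2]),
                       u = c(s1$u_printed[1, 1], s1$u_printed[1, 2]))
  pen <- data.frame(pi_a = s6$p_act[1, 3], pi_t = s6$p_tox[1, 3],
                    u = s6$u_printed[1, 3])
  w <- recover_utility_weights(no_pen, pen)
  expect_equal(w$omega1, 0.33)
  expect_equal(w$omega2, 1.09)
  # all 54 printed cells reproduced to the printed precision
  for (s in sc) {
    u <- compute_utility(s$p_act, s$p_tox, w)
    expect_lt(max(abs(u - s$u_printed)), 0.0005 + 1e-9)
  }
})

test_that("no single weight pair fits the printed table under the scaled penalty", {
  sc <- load_scenarios(paste0("S", 1:6))
  pa <- unlist(lapply(sc, function(s) as.vector(s$p_act)))
  pt <- unlist(lapply(sc, function(s) as.vector(s$p_tox)))
  u <- unlist(lapply(sc, function(s) as.vector(s$u_printed)))
  ind <- as.numeric(pt > 0.3)
  # least-squares (omega1, omega2) for U = pa - w1 pt - w2 pt 1(pt > phi)
  fit <- lm(I(u - pa) ~ 0 + I(-pt) + I(-pt * ind))
  expect_gt(max(abs(residuals(fit))), 0.01)
})

test_that("classification reproduces the published acceptable/good/correct structure", {
  sc <- load_scenarios(paste0("S", 1:6))
  acc <- table3_acceptable()
  corr <- table3_correct()
  for (nm in names(sc)) {
    cl <- classify_doses(sc[[nm]])
    expect_equal(cl$acceptable,
                 ij_matrix_to_logical(acc[[nm]], 3, 3),
                 info = nm)
    idx <- corr[[nm]][1] + (corr[[nm]][2] - 1) * 3
    expect_equal(which(cl$correct), idx, info = nm)
    # nesting: correct => good => acceptable
    expect_true(all(cl$acceptable[cl$good]), info = nm)
    expect_true(all(cl$good[cl$correct]), info = nm)
  }
  # default good tolerance gives the two top cells of S1
  cl1 <- classify_doses(sc$S1)
  expect_equal(which(cl1$good), c(3, 6))  # (3,1) and (3,2)
})

test_that("boundary conventions are non-strict and degenerate scenarios classify sanely", {
  g <- grid_2x5()
  # p_tox exactly 0.3 is safe; p_act exactly 0.2 is active
  s <- scenario_spec(g, matrix(0.3, 2, 5), matrix(0.2, 2, 5))
  cl <- classify_doses(s)
  expect_true(all(cl$acceptable))
  # ties in the utility maximum mark all tied cells correct
  expect_true(all(cl$correct))
  s_bad <- scenario_spec(g, matrix(0.9, 2, 5), matrix(0.9, 2, 5))
  expect_equal(sum(classify_doses(s_bad)$acceptable), 0)
  # T6 toxicity floor is 0.4 > 0.3: no acceptable cell whatever the activity
  t6 <- load_scenarios("T6.A1")[[1]]
  expect_equal(sum(classify_doses(t6)$acceptable), 0)
})

test_that("packaged fixtures load with the published values and validate input", {
  all <- load_scenarios()
  expect_length(all, 48 + 6)
  t1a1 <- all[["T1.A1"]]
  expect_equal(t1a1$p_tox[1, 1], 0.03)
  expect_equal(t1a1$p_act[1, 1], 0.20)
  expect_equal(dim(t1a1$p_tox), c(2L, 5L))
  expect_equal(all[["S5"]]$p_tox[3, 3], 0.45)
  expect_error(load_scenarios("T9.A1"), "unknown scenario")
  # malformed file: 2x4 matrix against a 2x5 grid
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("grid:", "  w1_doses: [600, 1200]",
               "  w2_doses: [50, 75, 100, 125, 150]",
               "scenarios:",
               "  B1:",
               "    p_tox:",
               "      - [0.1, 0.1, 0.1, 0.1]",
               "      - [0.1, 0.1, 0.1, 0.1]",
               "    p_act:",
               "      - [0.1, 0.1, 0.1, 0.1]",
               "      - [0.1, 0.1, 0.1, 0.1]"), bad)
  expect_error(load_scenarios(bad), "2 x 5")
  # out-of-range probability
  g <- grid_2x5()
  expect_error(scenario_spec(g, matrix(1.4, 2, 5), matrix(0.2, 2, 5)),
               "\\[0, 1\\]")
})

test_that("classification exports a complete per-cell table", {
  cl <- classify_doses(load_scenarios("S2")[[1]])
  f <- tempfile(fileext = ".csv")
  export_classification(cl, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 9)
  expect_named(tab, c("i", "j", "dose_w1", "dose_w2", "p_tox", "p_act",
                      "utility", "safe", "active", "acceptable", "good",
                      "correct"))
  expect_equal(sum(tab$correct), 1)
  expect_equal(tab$dose_w1[tab$correct], 1800)
  expect_equal(tab$dose_w2[tab$correct], 100)
})
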