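# Shared fixtures for the test suite.  All synthetic data are built in
# code under fixed seeds.

grid_2x5 <- function() dose_grid(c(600, 1200), c(50, 75, 100, 125, 150))
grid_3x3 <- function() dose_grid(c(600, 1200, 1800), c(50, 75, 100))

# Complete-follow-up observation table: one row per patient with weight 1.
complete_obs <- function(i, j, y_t, y_a) {
  data.frame(i = i, j = j, y_t = y_t, w_t = rep(1, length(i)),
             y_a = y_a, w_a = rep(1, length(i)))
}

# Random partially observed dataset for likelihood oracles.
random_obs <- function(n, ncells, seed) {
  set.seed(seed)
  data.frame(cell = sample.int(ncells, n, replace = TRUE),
             y_t = rbinom(n, 1, 0.3), y_a = rbinom(n, 1, 0.4),
             w_t = runif(n, 0.2, 1), w_a = runif(n, 0.2, 1))
}

# The acceptable (safe & active) cells of the published 3x3 scenario
# table, frozen from the italicised entries: list of (i, j) matrices.
table3_acceptable <- function() {
  list(
    S1 = rbind(c(2, 1), c(2, 2), c(2, 3), c(3, 1), c(3, 2)),
    S2 = rbind(c(3, 1), c(3, 2), c(3, 3)),
    S3 = rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 2), c(2, 3)),
    S4 = rbind(c(1, 1), c(1, 2), c(1, 3)),
    S5 = rbind(c(1, 3), c(2, 2), c(3, 1)),
    S6 = rbind(c(1, 2), c(2, 2), c(3, 2)))
}

# Correct (boldface) cell per scenario.
table3_correct <- function() {
  list(S1 = c(3, 2), S2 = c(3, 3), S3 = c(2, 3), S4 = c(1, 3),
       S5 = c(1, 3), S6 = c(3, 2))
}

ij_matrix_to_logical <- function(ij, I, J) {
  m <- matrix(FALSE, I, J)
  m[ij] <- TRUE
  m
}
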