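#' Dose grid for a two-agent combination trial
#'
#' Represents the \eqn{I \times J} grid of dose combinations \eqn{d_{ij}}
#' formed by \eqn{I} dose levels of agent W1 and \eqn{J} dose levels of
#' agent W2.  Rows of all per-grid matrices in the package index W1 levels
#' and columns index W2 levels.
#'
#' @param w1_doses Numeric vector of actual doses of agent W1 (e.g. mg),
#'   strictly increasing.
#' @param w2_doses Numeric vector of actual doses of agent W2
#'   (e.g. kBq/kg), strictly increasing.
#' @return An object of class `dose_grid` with elements `w1`, `w2`, `I`,
#'   `J` and `labels` (an `I x J` character matrix of `"dij"` labels).
#' @examples
#' dose_grid(c(600, 1200), c(50, 75, 100, 125, 150))
#' @export
dose_grid <- function(w1_doses, w2_doses) {
  stopifnot(is.numeric(w1_doses), is.numeric(w2_doses),
            length(w1_doses) >= 1, length(w2_doses) >= 1)
  if (any(diff(w1_doses) <= 0) || any(diff(w2_doses) <= 0))
    stop("dose values must be strictly increasing within each agent")
  I <- length(w1_doses)
  J <- length(w2_doses)
  labels <- outer(seq_len(I), seq_len(J), function(i, j) paste0("d", i, j))
  structure(list(w1 = as.numeric(w1_doses), w2 = as.numeric(w2_doses),
                 I = I, J = J, labels = labels),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d combinations\n", x$I, x$J))
  cat("  W1:", paste(x$w1, collapse = ", "), "\n")
  cat("  W2:", paste(x$w2, collapse = ", "), "\n")
  invisible(x)
}

#' Number of dose combinations in a grid
#' @param grid A [dose_grid()].
#' @return Integer, `I * J`.
#' @export
n_doses <- function(grid) grid$I * grid$J

## Cells are stored column-major (R matrix order): cell k = i + (j-1) * I.
cell_index <- function(grid, i, j) (j - 1L) * grid$I + i

cell_ij <- function(grid, k) {
  i <- ((k - 1L) %% grid$I) + 1L
  j <- ((k - 1L) %/% grid$I) + 1L
  cbind(i = i, j = j)
}

#' True-probability scenario for a dose grid
#'
#' Bundles a [dose_grid()] with the true probabilities of observing a
#' toxicity and an activity event over the full follow-up window of
#' \eqn{\tau} cycles at every dose combination.
#'
#' @param grid A [dose_grid()].
#' @param p_tox,p_act Numeric `I x J` matrices of window event
#'   probabilities (rows = W1 levels, columns = W2 levels).
#' @param label Scenario name, e.g. `"T2.A4"`.
#' @param u_printed Optional `I x J` matrix of externally tabulated true
#'   utilities (kept for reference/validation, not used by any design).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(grid, p_tox, p_act, label = "scenario",
                          u_printed = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  p_tox <- as.matrix(p_tox)
  p_act <- as.matrix(p_act)
  for (m in list(p_tox, p_act)) {
    if (!all(dim(m) == c(grid$I, grid$J)))
      stop(sprintf("probability matrix must be %d x %d", grid$I, grid$J))
    if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
      stop("probabilities must lie in [0, 1]")
  }
  if (!is.null(u_printed)) {
    u_printed <- as.matrix(u_printed)
    stopifnot(all(dim(u_printed) == c(grid$I, grid$J)))
  }
  structure(list(grid = grid, p_tox = p_tox, p_act = p_act,
                 label = label, u_printed = u_printed),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec '%s' (%d x %d)\n", x$label, x$grid$I, x$grid$J))
  cat("p_tox:\n"); print(x$p_tox)
  cat("p_act:\n"); print(x$p_act)
  invisible(x)
}

#' Utility trade-off parameters
#'
#' Parameters of the toxicity-activity trade-off utility
#' \deqn{U(\pi_A, \pi_T) = \pi_A - \omega_1 \pi_T - \mathrm{pen}(\pi_T)}
#' where the over-toxicity penalty is either a fixed amount
#' \eqn{\omega_2 1(\pi_T > \phi_T)} (`penalty_form = "fixed"`, the
#' default) or scales with the toxicity probability,
#' \eqn{\omega_2 \pi_T 1(\pi_T > \phi_T)} (`"scaled"`).  The two forms
#' agree exactly whenever \eqn{\pi_T \le \phi_T}; the fixed form is the
#' default because it is the only one consistent with the published true
#' utility tables (see the methods vignette).
#'
#' @param omega1 Trade-off weight for toxicity (default 0.33).
#' @param omega2 Over-toxicity penalty weight (default 1.09).
#' @param phi_t Toxicity target probability over the follow-up window
#'   (default 0.3); the penalty applies strictly above it.
#' @param penalty_form `"fixed"` or `"scaled"`.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(omega1 = 0.33, omega2 = 1.09, phi_t = 0.3,
                           penalty_form = c("fixed", "scaled")) {
  penalty_form <- match.arg(penalty_form)
  stopifnot(omega1 >= 0, omega2 >= 0, phi_t > 0, phi_t < 1)
  structure(list(omega1 = omega1, omega2 = omega2, phi_t = phi_t,
                 penalty_form = penalty_form),
            class = "utility_params")
}

#' Toxicity-activity trade-off utility
#'
#' @param pi_a,pi_t Probabilities of activity and toxicity over the
#'   follow-up window; vectorised (recycled to common length).
#' @param params A [utility_params()].
#' @return Numeric utility values.
#' @examples
#' compute_utility(0.20, 0.10)  # 0.167
#' @export
compute_utility <- function(pi_a, pi_t, params = utility_params()) {
  stopifnot(inherits(params, "utility_params"))
  if (any(pi_a < 0 | pi_a > 1, na.rm = TRUE) ||
      any(pi_t < 0 | pi_t > 1, na.rm = TRUE))
    stop("pi_a and pi_t must lie in [0, 1]")
  over <- pi_t > params$phi_t
  pen <- if (params$penalty_form == "fixed") params$omega2 * over
         else params$omega2 * pi_t * over
  pi_a - params$omega1 * pi_t - pen
}

#' Recover utility weights from tabulated utility cells
#'
#' Given two cells with toxicity at or below the target (no penalty) and
#' one cell above it, solves the utility definition exactly for
#' \eqn{(\omega_1, \omega_2)} by linear elimination:
#' \eqn{\omega_1 = ((\pi_{A,2}-\pi_{A,1}) - (U_2-U_1)) / (\pi_{T,2}-\pi_{T,1})}
#' from the two no-penalty cells, then
#' \eqn{\omega_2 = \pi_{A,3} - \omega_1\pi_{T,3} - U_3} from the
#' penalised cell (fixed-penalty form).
#'
#' @param no_pen A 2-row data frame / matrix with columns `pi_a`, `pi_t`,
#'   `u` for two cells with `pi_t <= phi_t`.
#' @param pen A 1-row data frame / matrix with the same columns for one
#'   cell with `pi_t > phi_t`.
#' @param phi_t Toxicity target (default 0.3).
#' @return A [utility_params()] with the recovered weights
#'   (fixed-penalty form).
#' @export
recover_utility_weights <- function(no_pen, pen, phi_t = 0.3) {
  no_pen <- as.data.frame(no_pen)
  pen <- as.data.frame(pen)
  stopifnot(nrow(no_pen) == 2, nrow(pen) == 1,
            all(c("pi_a", "pi_t", "u") %in% names(no_pen)),
            all(no_pen$pi_t <= phi_t), pen$pi_t > phi_t)
  d_pt <- no_pen$pi_t[2] - no_pen$pi_t[1]
  if (d_pt == 0) stop("the two no-penalty cells must differ in pi_t")
  omega1 <- ((no_pen$pi_a[2] - no_pen$pi_a[1]) -
             (no_pen$u[2] - no_pen$u[1])) / d_pt
  omega2 <- pen$pi_a - omega1 * pen$pi_t - pen$u
  utility_params(omega1 = omega1, omega2 = omega2, phi_t = phi_t,
                 penalty_form = "fixed")
}

#' Classify the dose combinations of a scenario
#'
#' Applies the true-probability definitions used to score final
#' selections: a combination is *safe* when its window toxicity
#' probability is at most `safe_cut`, *active* when its window activity
#' probability is at least `active_cut`, *acceptable* when both,
#' *correct* when it attains the maximum true utility among acceptable
#' combinations, and *good* when acceptable with utility within
#' `good_tolerance` of that maximum.  Ties in the maximum mark all tied
#' cells as correct.
#'
#' @param scenario A [scenario_spec()].
#' @param params A [utility_params()].
#' @param safe_cut Safety cutoff on `p_tox` (default 0.3, non-strict).
#' @param active_cut Activity cutoff on `p_act` (default 0.2, non-strict).
#' @param good_tolerance Absolute utility margin defining the good set
#'   (default 0.05).
#' @return An object of class `dose_classification`: logical `I x J`
#'   matrices `safe`, `active`, `acceptable`, `good`, `correct` and the
#'   numeric matrix `utility`.
#' @export
classify_doses <- function(scenario, params = utility_params(),
                           safe_cut = 0.3, active_cut = 0.2,
                           good_tolerance = 0.05) {
  stopifnot(inherits(scenario, "scenario_spec"))
  grid <- scenario$grid
  if (grid$I < 1 || grid$J < 1) stop("empty dose grid")
  u <- compute_utility(scenario$p_act, scenario$p_tox, params)
  dim(u) <- dim(scenario$p_tox)
  safe <- scenario$p_tox <= safe_cut
  active <- scenario$p_act >= active_cut
  acceptable <- safe & active
  correct <- good <- matrix(FALSE, grid$I, grid$J)
  if (any(acceptable)) {
    u_acc <- u[acceptable]
    u_max <- max(u_acc)
    correct[acceptable] <- u[acceptable] == u_max
    good[acceptable] <- u[acceptable] >= u_max - good_tolerance
  }
  structure(list(grid = grid, label = scenario$label, utility = u,
                 safe = safe, active = active, acceptable = acceptable,
                 good = good, correct = correct,
                 p_tox = scenario$p_tox, p_act = scenario$p_act,
                 good_tolerance = good_tolerance),
            class = "dose_classification")
}

#' Tabulate a dose classification
#'
#' @param x A `dose_classification` from [classify_doses()].
#' @param row.names,optional,... Passed for S3 compatibility (unused).
#' @return A data frame with one row per dose combination and columns
#'   `i`, `j`, `dose_w1`, `dose_w2`, `p_tox`, `p_act`, `utility`,
#'   `safe`, `active`, `acceptable`, `good`, `correct`.
#' @export
as.data.frame.dose_classification <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  g <- x$grid
  ij <- cell_ij(g, seq_len(n_doses(g)))
  data.frame(i = ij[, "i"], j = ij[, "j"],
             dose_w1 = g$w1[ij[, "i"]], dose_w2 = g$w2[ij[, "j"]],
             p_tox = as.vector(x$p_tox), p_act = as.vector(x$p_act),
             utility = as.vector(x$utility), safe = as.vector(x$safe),
             active = as.vector(x$active),
             acceptable = as.vector(x$acceptable),
             good = as.vector(x$good), correct = as.vector(x$correct))
}

#' Export a dose classification as CSV
#' @param x A `dose_classification`.
#' @param file Path to write.
#' @return Invisibly, the data frame written.
#' @export
export_classification <- function(x, file) {
  df <- as.data.frame(x)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

as_prob_matrix <- function(x, I, J, what) {
  m <- do.call(rbind, lapply(x, as.numeric))
  if (!is.matrix(m) || nrow(m) != I || ncol(m) != J)
    stop(sprintf("%s must be a %d x %d matrix", what, I, J))
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop(sprintf("%s values must lie in [0, 1]", what))
  m
}

load_scenario_file <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(spec$grid$w1_doses) || is.null(spec$grid$w2_doses))
    stop("scenario file must declare grid.w1_doses and grid.w2_doses")
  grid <- dose_grid(spec$grid$w1_doses, spec$grid$w2_doses)
  out <- list()
  if (!is.null(spec$scenarios)) {
    for (nm in names(spec$scenarios)) {
      sc <- spec$scenarios[[nm]]
      up <- if (!is.null(sc$u_printed))
        do.call(rbind, lapply(sc$u_printed, as.numeric))
      out[[nm]] <- scenario_spec(
        grid,
        as_prob_matrix(sc$p_tox, grid$I, grid$J, paste0(nm, " p_tox")),
        as_prob_matrix(sc$p_act, grid$I, grid$J, paste0(nm, " p_act")),
        label = nm, u_printed = up)
    }
  }
  if (!is.null(spec$toxicity) && !is.null(spec$activity)) {
    tox <- lapply(spec$toxicity, as_prob_matrix, I = grid$I, J = grid$J,
                  what = "toxicity")
    act <- lapply(spec$activity, as_prob_matrix, I = grid$I, J = grid$J,
                  what = "activity")
    for (tn in names(tox)) for (an in names(act)) {
      nm <- paste0(tn, ".", an)
      out[[nm]] <- scenario_spec(grid, tox[[tn]], act[[an]], label = nm)
    }
  }
  if (!length(out)) stop("no scenarios found in ", path)
  out
}

builtin_scenario_files <- function() {
  c(system.file("extdata", "scenarios_2x5.yaml", package = "dualtite"),
    system.file("extdata", "scenarios_3x3.yaml", package = "dualtite"))
}

#' Load trial scenarios
#'
#' Reads scenario specifications either from a YAML/JSON file or, when
#' given scenario names such as `"T2.A4"` or `"S5"`, from the packaged
#' fixtures covering the 48 combinations of toxicity profiles T1-T6 with
#' activity profiles A1-A8 on the 2 x 5 grid, and S1-S6 on the 3 x 3
#' grid.
#'
#' File format (YAML or JSON): a `grid` block with `w1_doses` and
#' `w2_doses`, plus either named `scenarios` each holding row-major
#' `p_tox` / `p_act` matrices (rows = W1 levels), or `toxicity` and
#' `activity` blocks of named profile matrices that are crossed into
#' `<tox>.<act>` scenarios.
#'
#' @param x A file path, or a character vector of packaged scenario
#'   names, or `NULL` to return every packaged scenario.
#' @return A named list of [scenario_spec()] objects.
#' @examples
#' s <- load_scenarios("T1.A1")[["T1.A1"]]
#' s$p_tox[1, 1]  # 0.03
#' @export
load_scenarios <- function(x = NULL) {
  if (length(x) == 1 && file.exists(x)) return(load_scenario_file(x))
  all <- do.call(c, lapply(builtin_scenario_files(), load_scenario_file))
  if (is.null(x)) return(all)
  missing <- setdiff(x, names(all))
  if (length(missing))
    stop("unknown scenario name(s): ", paste(missing, collapse = ", "))
  all[x]
}
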