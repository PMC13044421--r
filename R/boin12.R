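#' BOIN escalation and de-escalation boundaries
#'
#' Closed-form optimal interval boundaries for target DLT rate
#' \eqn{\phi} with sub-/over-dosing references \eqn{\phi_1 < \phi <
#' \phi_2}:
#' \deqn{\lambda_e = \frac{\log((1-\phi_1)/(1-\phi))}
#'   {\log(\phi(1-\phi_1)/(\phi_1(1-\phi)))}, \qquad
#'   \lambda_d = \frac{\log((1-\phi)/(1-\phi_2))}
#'   {\log(\phi_2(1-\phi)/(\phi(1-\phi_2)))}.}
#'
#' @param phi Target window-toxicity probability (default 0.3).
#' @param phi1,phi2 Sub-/over-dosing references (defaults `0.6 phi` and
#'   `1.4 phi`).
#' @return List with `lambda_e` and `lambda_d`;
#'   `lambda_e < phi < lambda_d` always.
#' @export
boin_boundaries <- function(phi = 0.3, phi1 = 0.6 * phi, phi2 = 1.4 * phi) {
  stopifnot(phi1 > 0, phi1 < phi, phi < phi2, phi2 < 1)
  lambda_e <- log((1 - phi1) / (1 - phi)) /
    log(phi * (1 - phi1) / (phi1 * (1 - phi)))
  lambda_d <- log((1 - phi) / (1 - phi2)) /
    log(phi2 * (1 - phi) / (phi * (1 - phi2)))
  list(lambda_e = lambda_e, lambda_d = lambda_d)
}

#' TITE-imputed effective event counts per dose combination
#'
#' Events count 1 towards the effective sample size; pending patients
#' without the event contribute their fraction of completed follow-up
#' (the same TITE weights used by the model-based designs).  With all
#' patients fully observed this equals the raw counts.
#'
#' @param records A [patient_records()] table.
#' @param now Analysis time (cycles).
#' @return Data frame with columns `i`, `j`, `n`, `y_t`, `ess_t`, `y_a`,
#'   `ess_a`, one row per dose combination with enrolled patients.
#' @export
tite_effective_counts <- function(records, now) {
  if (!nrow(records))
    return(data.frame(i = integer(0), j = integer(0), n = integer(0),
                      y_t = numeric(0), ess_t = numeric(0),
                      y_a = numeric(0), ess_a = numeric(0)))
  obs <- observe(records, now)
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(obs)),
                                y_t = obs$y_t, ess_t = obs$w_t,
                                y_a = obs$y_a, ess_a = obs$w_a) ~ i + j,
                          data = obs, FUN = sum)
  agg[order(agg$i, agg$j), c("i", "j", "n", "y_t", "ess_t", "y_a", "ess_a")]
}

#' TITE-comb-BOIN12 design configuration
#'
#' Model-assisted comparator: per-dose decisions from interval
#' comparisons of the TITE-imputed DLT rate against the BOIN boundaries,
#' with Beta(1, 1) per-dose posteriors supplying admissibility and a
#' posterior-mean utility ranking among candidate neighbour moves.
#'
#' @param phi Target window-toxicity probability (default 0.3).
#' @param phi1,phi2 Interval references (defaults `0.6 phi`, `1.4 phi`).
#' @param utility A [utility_params()] (the shared trade-off utility).
#' @return An object of class `c("boin12_design", "dualtite_design")`.
#' @export
boin12_design <- function(phi = 0.3, phi1 = 0.6 * phi, phi2 = 1.4 * phi,
                          utility = utility_params()) {
  b <- boin_boundaries(phi, phi1, phi2)
  structure(list(phi = phi, phi1 = phi1, phi2 = phi2,
                 lambda_e = b$lambda_e, lambda_d = b$lambda_d,
                 utility = utility),
            class = c("boin12_design", "dualtite_design"))
}

## Per-dose Beta(1, 1) posterior quantities from effective counts.
beta_post_params <- function(counts, grid) {
  ncell <- n_doses(grid)
  a_t <- b_t <- a_a <- b_a <- rep(1, ncell)
  if (nrow(counts)) {
    k <- cell_index(grid, counts$i, counts$j)
    a_t[k] <- 1 + counts$y_t
    b_t[k] <- 1 + pmax(counts$ess_t - counts$y_t, 0)
    a_a[k] <- 1 + counts$y_a
    b_a[k] <- 1 + pmax(counts$ess_a - counts$y_a, 0)
  }
  list(a_t = a_t, b_t = b_t, a_a = a_a, b_a = b_a)
}

## Admissibility under the shared criteria, evaluated with the closed
## Beta posterior: P(pi_T < phi_T) > q_T and P(pi_A > phi_A) > q_A.
boin_admissible <- function(bp, adm) {
  p_safe <- stats::pbeta(adm$phi_t, bp$a_t, bp$b_t)
  p_act <- 1 - stats::pbeta(adm$phi_a, bp$a_a, bp$b_a)
  p_safe > adm$q_t & p_act > adm$q_a
}

boin_utility_means <- function(bp, utility) {
  compute_utility(bp$a_a / (bp$a_a + bp$b_a),
                  bp$a_t / (bp$a_t + bp$b_t), utility)
}

#' TITE-comb-BOIN12 dosing decision
#'
#' Compares the TITE-imputed DLT rate at the current dose combination
#' with the BOIN boundaries to set the move direction, then ranks the
#' admissible candidate combinations by Beta-posterior-mean utility:
#'
#' * rate \eqn{\le \lambda_e}: escalation preferred - the admissible
#'   escalation neighbour (one agent up one level) with the highest
#'   posterior-mean utility; falling back to staying, then to
#'   de-escalation neighbours;
#' * \eqn{\lambda_e <} rate \eqn{< \lambda_d}: stay if admissible, else
#'   the best admissible de-escalation neighbour;
#' * rate \eqn{\ge \lambda_d}: de-escalation only.
#'
#' Candidates must also be allowable under the dose-skipping rule and
#' not excluded by hard safety.  Ties prefer staying, then the lowest
#' `(i, j)`.  Returns `NULL` when no candidate is admissible (the trial
#' loop translates this into a no-admissible-dose stop).
#'
#' @param records A [patient_records()] table.
#' @param now Analysis time (cycles).
#' @param current Length-2 integer vector, the current dose `(i, j)`.
#' @param grid A [dose_grid()].
#' @param design A [boin12_design()].
#' @param adm An [admissibility_params()].
#' @param allowable Matrix/set of allowable cells from
#'   [allowable_doses()] (integer cell indices).
#' @return Length-2 integer vector `(i, j)` or `NULL`.
#' @export
boin12_decision <- function(records, now, current, grid, design,
                            adm = admissibility_params(),
                            allowable = seq_len(n_doses(grid))) {
  counts <- tite_effective_counts(records, now)
  bp <- beta_post_params(counts, grid)
  admissible <- boin_admissible(bp, adm)
  util <- boin_utility_means(bp, design$utility)
  ok <- function(i, j) {
    if (i < 1 || i > grid$I || j < 1 || j > grid$J) return(FALSE)
    k <- cell_index(grid, i, j)
    (k %in% allowable) && admissible[k]
  }
  cur_k <- cell_index(grid, current[1], current[2])
  row <- counts[counts$i == current[1] & counts$j == current[2], ]
  rate <- if (nrow(row) && row$ess_t > 0) row$y_t / row$ess_t else 0
  esc <- list(current + c(1L, 0L), current + c(0L, 1L))
  desc <- list(current - c(1L, 0L), current - c(0L, 1L))
  pick_best <- function(moves) {
    keep <- Filter(function(d) ok(d[1], d[2]), moves)
    if (!length(keep)) return(NULL)
    us <- vapply(keep, function(d) util[cell_index(grid, d[1], d[2])], 0)
    best <- us >= max(us) - 1e-12
    cand <- keep[best]
    stay <- Filter(function(d) all(d == current), cand)
    if (length(stay)) return(stay[[1]])
    ord <- order(vapply(cand, function(d) d[1], numeric(1)),
                 vapply(cand, function(d) d[2], numeric(1)))
    cand[[ord[1]]]
  }
  tiers <- if (rate >= design$lambda_d) {
    list(desc)
  } else if (rate <= design$lambda_e) {
    list(esc, list(current), desc)
  } else {
    list(list(current), desc)
  }
  for (tier in tiers) {
    sel <- pick_best(tier)
    if (!is.null(sel)) return(as.integer(sel))
  }
  NULL
}

## Final recommendation for the BOIN arm: best posterior-mean utility
## among admissible, allowable, non-excluded cells on complete data.
boin_select <- function(records, now, grid, design, adm, allowable) {
  counts <- tite_effective_counts(records, now)
  bp <- beta_post_params(counts, grid)
  admissible <- boin_admissible(bp, adm)
  util <- boin_utility_means(bp, design$utility)
  cand <- intersect(which(admissible), allowable)
  ## only combinations with data support a final recommendation
  explored <- if (nrow(counts)) cell_index(grid, counts$i, counts$j)
              else integer(0)
  cand <- intersect(cand, explored)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(util[cand])]
  as.integer(cell_ij(grid, best)[1, ])
}
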