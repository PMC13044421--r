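#' Admissibility thresholds
#'
#' A dose combination is admissible when the posterior evidence that it
#' is safe and active clears both thresholds:
#' \eqn{P(\pi_T < \phi_T) > q_T} and \eqn{P(\pi_A > \phi_A) > q_A},
#' with the probabilities taken over the follow-up window.
#'
#' @param phi_t Toxicity target (default 0.3).
#' @param phi_a Activity target (default 0.2).
#' @param q_t,q_a Posterior-probability thresholds (defaults 0.2).
#' @return An object of class `admissibility_params`.
#' @export
admissibility_params <- function(phi_t = 0.3, phi_a = 0.2,
                                 q_t = 0.2, q_a = 0.2) {
  stopifnot(phi_t > 0, phi_t < 1, phi_a > 0, phi_a < 1,
            q_t > 0, q_t < 1, q_a > 0, q_a < 1)
  structure(list(phi_t = phi_t, phi_a = phi_a, q_t = q_t, q_a = q_a),
            class = "admissibility_params")
}

#' Trial configuration shared by all designs
#'
#' @param cohort_size Patients per cohort (default 3).
#' @param start_dose Starting combination `(i, j)` (default `c(2, 2)`).
#' @param tau Follow-up window in cycles (default 3).
#' @param c_suff Sufficient-information cut-off: the trial stops when
#'   the recommended next combination already carries this many patients
#'   (default 30).
#' @param n_max Maximum number of patients (default 60).
#' @param adm An [admissibility_params()].
#' @param utility A [utility_params()].
#' @param hard_safety_p0 Cycle-1 DLT probability in the hard-safety
#'   criterion (default 0.3).
#' @param conf_exclude Posterior probability needed to exclude a dose
#'   under hard safety (default 0.95).
#' @param conf_stop Posterior probability in the lowest-unsafe /
#'   highest-very-safe stopping rules (default 0.80).
#' @param rho Latent correlation of the outcome generator
#'   (default -0.5).
#' @param tox_cycle1_fraction Fraction of window toxicity probability in
#'   cycle 1 (default 0.75).
#' @param final_fit When `TRUE` (default) the final recommendation is
#'   recomputed from complete follow-up of all enrolled patients; when
#'   `FALSE` the last interim decision stands.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(cohort_size = 3, start_dose = c(2, 2), tau = 3,
                         c_suff = 30, n_max = 60,
                         adm = admissibility_params(),
                         utility = utility_params(),
                         hard_safety_p0 = 0.3, conf_exclude = 0.95,
                         conf_stop = 0.80, rho = -0.5,
                         tox_cycle1_fraction = 0.75, final_fit = TRUE) {
  stopifnot(cohort_size >= 1, length(start_dose) == 2, tau > 0,
            c_suff >= 1, n_max >= cohort_size,
            hard_safety_p0 > 0, hard_safety_p0 < 1,
            conf_exclude > 0, conf_exclude < 1,
            conf_stop > 0, conf_stop < 1)
  structure(list(cohort_size = as.integer(cohort_size),
                 start_dose = as.integer(start_dose), tau = tau,
                 c_suff = as.integer(c_suff), n_max = as.integer(n_max),
                 adm = adm, utility = utility,
                 hard_safety_p0 = hard_safety_p0,
                 conf_exclude = conf_exclude, conf_stop = conf_stop,
                 rho = rho, tox_cycle1_fraction = tox_cycle1_fraction,
                 final_fit = final_fit),
            class = "trial_config")
}

#' Allowable dose combinations under the dose-skipping rule
#'
#' Once combination \eqn{(i^*, j^*)} has been explored, all \eqn{(i, j)}
#' with \eqn{i \le i^*} and \eqn{j \le j^* + 1}, or \eqn{i \le i^* + 1}
#' and \eqn{j \le j^*}, become allowable: no dose level of either agent
#' can be skipped and escalation cannot proceed in both agents at once.
#'
#' @param explored Integer vector of explored cell indices
#'   (column-major, `k = i + (j-1) I`), or an n x 2 matrix of `(i, j)`.
#' @param grid A [dose_grid()].
#' @return Sorted integer vector of allowable cell indices.
#' @export
allowable_doses <- function(explored, grid) {
  if (is.matrix(explored))
    explored <- cell_index(grid, explored[, 1], explored[, 2])
  if (!length(explored)) return(integer(0))
  ij <- cell_ij(grid, explored)
  allow <- matrix(FALSE, grid$I, grid$J)
  ii <- row(allow)
  jj <- col(allow)
  for (r in seq_len(nrow(ij))) {
    allow <- allow |
      (ii <= ij[r, "i"] & jj <= ij[r, "j"] + 1) |
      (ii <= ij[r, "i"] + 1 & jj <= ij[r, "j"])
  }
  which(allow)
}

#' Posterior probability that an event rate exceeds a bound
#'
#' Beta-binomial model with a Beta(1, 1) prior:
#' \eqn{P(p > p_0 \mid y, n) = 1 - F_{Beta(1+y,\,1+n-y)}(p_0)}.
#'
#' @param y Number of events.
#' @param n Number of patients (allows non-integer effective counts).
#' @param p0 Probability bound.
#' @return Posterior probability; vectorised.
#' @export
posterior_prob_exceed <- function(y, n, p0) {
  stopifnot(all(y >= 0), all(y <= n + 1e-9))
  1 - stats::pbeta(p0, 1 + y, 1 + n - y)
}

#' Hard-safety exclusions from cycle-1 DLT counts
#'
#' A combination \eqn{(i^*, j^*)} triggers when
#' \eqn{P(p_1 > p_0) > } `conf` under the Beta(1, 1) posterior on its
#' cycle-1 DLT rate; at the default `p0 = 0.3`, `conf = 0.95` this
#' reproduces the count boundaries 3/3, 4/6 and 5/9.  On trigger, every
#' combination at the same or higher dose level of both agents is
#' excluded from further exploration.
#'
#' @param counts Data frame from [cycle1_dlt_counts()].
#' @param grid A [dose_grid()].
#' @param p0,conf Criterion parameters.
#' @return Sorted integer vector of excluded cell indices.
#' @export
hard_safety_exclusions <- function(counts, grid, p0 = 0.3, conf = 0.95) {
  if (!nrow(counts)) return(integer(0))
  trig <- posterior_prob_exceed(counts$y, counts$n, p0) > conf
  if (!any(trig)) return(integer(0))
  excl <- matrix(FALSE, grid$I, grid$J)
  ii <- row(excl)
  jj <- col(excl)
  for (r in which(trig))
    excl <- excl | (ii >= counts$i[r] & jj >= counts$j[r])
  which(excl)
}

#' Admissible dose combinations from a fitted posterior
#'
#' @param posterior A `posterior_summary` (matrices `pi_t`, `pi_a` of
#'   draws by dose cells).
#' @param adm An [admissibility_params()].
#' @return Integer vector of admissible cell indices.
#' @export
admissible_set <- function(posterior, adm = admissibility_params()) {
  p_safe <- colMeans(posterior$pi_t < adm$phi_t)
  p_act <- colMeans(posterior$pi_a > adm$phi_a)
  which(p_safe > adm$q_t & p_act > adm$q_a)
}

#' Select the candidate dose with highest posterior mean utility
#'
#' The utility is evaluated draw-by-draw on the joint posterior of
#' \eqn{(\pi_A, \pi_T)} and averaged; ties are broken towards the lowest
#' `(i, j)`.
#'
#' @param posterior A `posterior_summary`.
#' @param candidates Integer vector of candidate cell indices.
#' @param grid A [dose_grid()].
#' @param utility A [utility_params()].
#' @return Length-2 integer vector `(i, j)`, or `NULL` when
#'   `candidates` is empty.
#' @export
select_dose <- function(posterior, candidates, grid,
                        utility = utility_params()) {
  if (!length(candidates)) return(NULL)
  u <- vapply(candidates, function(k)
    mean(compute_utility(posterior$pi_a[, k], posterior$pi_t[, k],
                         utility)), 0)
  best <- candidates[u >= max(u) - 1e-12]
  ij <- cell_ij(grid, best)
  ord <- order(ij[, "i"], ij[, "j"])
  as.integer(ij[ord[1], ])
}

cycle1_at <- function(counts, i, j) {
  r <- counts[counts$i == i & counts$j == j, ]
  if (nrow(r)) c(y = r$y, n = r$n) else c(y = 0, n = 0)
}

#' Run one simulated trial
#'
#' Simulates a complete trial of the given design on a scenario:
#' cohorts enter one cycle apart starting at the configured start dose;
#' every decision uses all data observed at the decision clock through
#' the TITE weights; the enforcement rules (dose skipping, hard safety)
#' and the six stopping rules are applied in the fixed order
#' hard-safety-all, lowest-unsafe, no-admissible, highest-very-safe,
#' sufficient-information, maximum-patients.  On stopping with a
#' selectable reason the final recommendation is recomputed after all
#' enrolled patients complete their follow-up (unless
#' `config$final_fit = FALSE`).
#'
#' @param design A [pocrm_design()], [blrm_design()] or
#'   [boin12_design()].
#' @param scenario A [scenario_spec()].
#' @param config A [trial_config()].
#' @param seed Integer seed; the whole trial is reproducible from it.
#' @return An object of class `trial_result`: `stop_reason` (one of
#'   `no_admissible`, `lowest_unsafe`, `highest_very_safe`,
#'   `sufficient_info`, `hard_safety_all`, `max_patients`),
#'   `recommendation` (`c(i, j)` or `NULL`), `n_patients`, `assignments`
#'   (`I x J` matrix), `records`, `explored`, `excluded`, and a
#'   per-decision `trace`.
#' @export
run_trial <- function(design, scenario, config = trial_config(),
                      seed = 1) {
  stopifnot(inherits(design, "dualtite_design"),
            inherits(scenario, "scenario_spec"),
            inherits(config, "trial_config"))
  set.seed(seed)
  grid <- scenario$grid
  is_boin <- inherits(design, "boin12_design")
  none_reasons <- c("no_admissible", "lowest_unsafe", "hard_safety_all")

  current <- config$start_dose
  records <- simulate_patients(scenario, current, entry = 0,
                               n_patients = config$cohort_size,
                               first_id = 1L, cohort_id = 1L,
                               tau = config$tau, rho = config$rho,
                               tox_cycle1_fraction =
                                 config$tox_cycle1_fraction)
  explored <- cell_index(grid, current[1], current[2])
  excluded <- integer(0)
  n_cohorts <- 1L
  trace <- list()
  stop_reason <- NULL
  last_posterior <- NULL

  repeat {
    now <- n_cohorts  # previous cohort has one full cycle of follow-up
    obs <- observe(records, now)
    c1 <- cycle1_dlt_counts(records, now)
    excluded <- sort(union(excluded,
                           hard_safety_exclusions(c1, grid,
                                                  config$hard_safety_p0,
                                                  config$conf_exclude)))
    if (cell_index(grid, 1L, 1L) %in% excluded) {
      stop_reason <- "hard_safety_all"; break
    }
    low <- cycle1_at(c1, 1L, 1L)
    if (low["n"] >= config$cohort_size &&
        posterior_prob_exceed(low["y"], low["n"],
                              config$hard_safety_p0) > config$conf_stop) {
      stop_reason <- "lowest_unsafe"; break
    }
    allowable <- setdiff(allowable_doses(explored, grid), excluded)
    if (is_boin) {
      next_dose <- boin12_decision(records, now, current, grid, design,
                                   config$adm, allowable)
      if (is.null(next_dose)) { stop_reason <- "no_admissible"; break }
    } else {
      last_posterior <- fit_design(design, obs, grid)
      cand <- intersect(admissible_set(last_posterior, config$adm),
                        allowable)
      next_dose <- select_dose(last_posterior, cand, grid, config$utility)
      if (is.null(next_dose)) { stop_reason <- "no_admissible"; break }
    }
    high <- cycle1_at(c1, grid$I, grid$J)
    if (high["n"] >= config$cohort_size &&
        stats::pbeta(config$hard_safety_p0, 1 + high["y"],
                     1 + high["n"] - high["y"]) > config$conf_stop) {
      stop_reason <- "highest_very_safe"; break
    }
    n_at_next <- sum(records$i == next_dose[1] & records$j == next_dose[2])
    if (n_at_next >= config$c_suff) {
      stop_reason <- "sufficient_info"; break
    }
    if (nrow(records) >= config$n_max) {
      stop_reason <- "max_patients"; break
    }
    trace[[length(trace) + 1]] <-
      list(decision_time = now, next_dose = next_dose,
           n_enrolled = nrow(records))
    current <- next_dose
    records <- rbind(records,
                     simulate_patients(scenario, current, entry = now,
                                       n_patients = config$cohort_size,
                                       first_id = nrow(records) + 1L,
                                       cohort_id = n_cohorts + 1L,
                                       tau = config$tau, rho = config$rho,
                                       tox_cycle1_fraction =
                                         config$tox_cycle1_fraction))
    explored <- sort(union(explored,
                           cell_index(grid, current[1], current[2])))
    n_cohorts <- n_cohorts + 1L
  }

  ## final analysis on complete follow-up of all enrolled patients
  recommendation <- NULL
  if (!(stop_reason %in% none_reasons)) {
    final_now <- max(records$entry) + config$tau
    c1_full <- cycle1_dlt_counts(records, final_now)
    excluded <- sort(union(excluded,
                           hard_safety_exclusions(c1_full, grid,
                                                  config$hard_safety_p0,
                                                  config$conf_exclude)))
    allowable <- setdiff(allowable_doses(explored, grid), excluded)
    if (is_boin) {
      recommendation <- boin_select(records, final_now, grid, design,
                                    config$adm, allowable)
    } else if (config$final_fit || is.null(last_posterior)) {
      obs_full <- observe(records, final_now)
      post <- fit_design(design, obs_full, grid)
      cand <- intersect(admissible_set(post, config$adm), allowable)
      recommendation <- select_dose(post, cand, grid, config$utility)
    } else {
      cand <- intersect(admissible_set(last_posterior, config$adm),
                        allowable)
      recommendation <- select_dose(last_posterior, cand, grid,
                                    config$utility)
    }
  }

  assignments <- matrix(0L, grid$I, grid$J)
  tab <- table(factor(cell_index(grid, records$i, records$j),
                      levels = seq_len(n_doses(grid))))
  assignments[] <- as.integer(tab)
  structure(list(stop_reason = stop_reason,
                 recommendation = recommendation,
                 n_patients = nrow(records), assignments = assignments,
                 records = records, explored = explored,
                 excluded = excluded, trace = trace,
                 scenario = scenario$label,
                 design = class(design)[1], seed = seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  rec <- if (is.null(x$recommendation)) "none"
         else sprintf("(%d, %d)", x$recommendation[1], x$recommendation[2])
  cat(sprintf("trial_result [%s on %s]: stop=%s, recommendation=%s, n=%d\n",
              x$design, x$scenario, x$stop_reason, rec, x$n_patients))
  invisible(x)
}

#' Export a trial result
#'
#' Writes the stop reason, recommendation, assignment counts and
#' decision trace as JSON, and optionally the patient listing as CSV.
#'
#' @param result A `trial_result`.
#' @param json_file Path for the JSON summary (`NULL` to skip).
#' @param csv_file Path for the patient listing CSV (`NULL` to skip).
#' @return Invisibly, the list serialised to JSON.
#' @export
export_trial_result <- function(result, json_file = NULL, csv_file = NULL) {
  out <- list(design = result$design, scenario = result$scenario,
              seed = result$seed, stop_reason = result$stop_reason,
              recommendation = result$recommendation,
              n_patients = result$n_patients,
              assignments = result$assignments,
              excluded_cells = result$excluded,
              trace = result$trace)
  if (!is.null(json_file))
    jsonlite::write_json(out, json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(csv_file))
    utils::write.csv(result$records, csv_file, row.names = FALSE)
  invisible(out)
}
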