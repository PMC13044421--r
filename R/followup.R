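#' Patient record table
#'
#' Constructs the per-patient bookkeeping table used throughout the
#' package: dose assignment, entry time on the trial clock, the latent
#' event times for toxicity and activity (possibly `Inf`), and the
#' follow-up length \eqn{\tau}.  All times are measured in treatment
#' cycles; calendar time never enters any computation.
#'
#' @param patient_id Integer ids.
#' @param cohort_id Integer cohort ids.
#' @param i,j Dose-combination indices (1-based; `i` indexes agent W1
#'   levels, `j` agent W2 levels).
#' @param entry Entry times in cycles (>= 0).
#' @param t_tox,t_act Latent event times in cycles measured from entry
#'   (> 0, `Inf` when the event never occurs).
#' @param tau Follow-up window in cycles (default 3).
#' @return A data frame of class `patient_records`.
#' @export
patient_records <- function(patient_id, cohort_id, i, j, entry,
                            t_tox, t_act, tau = 3) {
  stopifnot(all(entry >= 0), all(t_tox > 0), all(t_act > 0), tau > 0)
  structure(data.frame(patient_id = as.integer(patient_id),
                       cohort_id = as.integer(cohort_id),
                       i = as.integer(i), j = as.integer(j),
                       entry = as.numeric(entry),
                       t_tox = as.numeric(t_tox),
                       t_act = as.numeric(t_act),
                       tau = as.numeric(tau)),
            class = c("patient_records", "data.frame"))
}

empty_records <- function(tau = 3) {
  patient_records(integer(0), integer(0), integer(0), integer(0),
                  numeric(0), numeric(0), numeric(0), tau = tau)
}

#' Observed outcomes and TITE weights at an analysis time
#'
#' Computes, for every patient, the binary indicators and time-to-event
#' weights available at trial clock `now`.  A toxicity is observed
#' (`y_t = 1`, `w_t = 1`) when its latent time falls within the elapsed
#' follow-up `min(now - entry, tau)`; otherwise `w_t` is the fraction of
#' follow-up completed.  An activity response is observed only if it
#' occurs before any DLT; when a DLT occurs first the activity
#' observation is censored at the DLT time, contributing weight
#' `t_tox / tau`.  Events at exactly the follow-up boundary count as
#' observed.
#'
#' @param records A [patient_records()] table.
#' @param now Analysis time on the trial clock (cycles); must be at or
#'   after every entry time.
#' @return A data frame with columns `patient_id`, `i`, `j`,
#'   `follow_up`, `y_t`, `w_t`, `y_a`, `w_a`.
#' @export
observe <- function(records, now) {
  if (nrow(records) && any(now < records$entry))
    stop("analysis time precedes the entry time of some patients")
  fu <- pmin(now - records$entry, records$tau)
  y_t <- as.integer(records$t_tox <= fu)
  w_t <- ifelse(y_t == 1, 1, fu / records$tau)
  ## activity is censored by an observed DLT occurring first
  y_a <- as.integer(records$t_act <= pmin(fu, records$t_tox))
  w_a <- ifelse(y_a == 1, 1,
                ifelse(y_t == 1 & records$t_tox < records$t_act,
                       records$t_tox / records$tau,
                       fu / records$tau))
  data.frame(patient_id = records$patient_id, i = records$i,
             j = records$j, follow_up = fu,
             y_t = y_t, w_t = w_t, y_a = y_a, w_a = w_a)
}

#' First-cycle DLT counts per dose combination
#'
#' Counts, for each dose combination, the number of patients with at
#' least one full cycle of follow-up at time `now` (`n`) and how many of
#' them had a DLT within the first cycle (`y`).  Patients with under one
#' cycle of follow-up are excluded from the denominator.  These counts
#' feed the hard-safety enforcement rule and the cycle-1 beta-binomial
#' stopping rules.
#'
#' @param records A [patient_records()] table.
#' @param now Analysis time (cycles).
#' @return A data frame with columns `i`, `j`, `y`, `n`, one row per
#'   dose combination with `n > 0` (zero rows if none).
#' @export
cycle1_dlt_counts <- function(records, now) {
  if (!nrow(records))
    return(data.frame(i = integer(0), j = integer(0),
                      y = integer(0), n = integer(0)))
  fu <- pmin(now - records$entry, records$tau)
  keep <- fu >= 1
  if (!any(keep))
    return(data.frame(i = integer(0), j = integer(0),
                      y = integer(0), n = integer(0)))
  r <- records[keep, ]
  agg <- stats::aggregate(cbind(y = as.integer(r$t_tox <= 1),
                                n = rep(1L, nrow(r))) ~ i + j, data = r,
                          FUN = sum)
  agg[order(agg$i, agg$j), c("i", "j", "y", "n")]
}
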