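#' Score one trial result against the scenario truth
#'
#' @param result A `trial_result`.
#' @param classification A `dose_classification` from [classify_doses()]
#'   for the same scenario.
#' @return A one-row data frame with the selection class (`correct`,
#'   `good`, `acceptable`, `unacceptable`, `none`; classes are nested,
#'   so a correct selection is also good and acceptable), total sample
#'   size, patients on truly unsafe combinations, and the stop reason.
#' @export
score_trial <- function(result, classification) {
  rec <- result$recommendation
  cls <- if (is.null(rec)) "none" else {
    i <- rec[1]; j <- rec[2]
    if (classification$correct[i, j]) "correct"
    else if (classification$good[i, j]) "good"
    else if (classification$acceptable[i, j]) "acceptable"
    else "unacceptable"
  }
  unsafe <- !classification$safe
  data.frame(selection = cls,
             n_patients = result$n_patients,
             n_unsafe = sum(result$assignments[unsafe]),
             stop_reason = result$stop_reason)
}

#' Run a simulation study
#'
#' Replicates [run_trial()] over one or more scenarios, scoring every
#' replicate against the true dose classification.  Per-replicate seeds
#' are derived deterministically from the master seed, so results do not
#' depend on evaluation order or worker count.
#'
#' @param design A design object ([pocrm_design()], [blrm_design()],
#'   [boin12_design()]).
#' @param scenarios A named list of [scenario_spec()] (or a character
#'   vector of packaged scenario names, see [load_scenarios()]).
#' @param n_sims Replicates per scenario (default 100; the published
#'   operating characteristics use 1000).
#' @param master_seed Master seed.
#' @param config A [trial_config()].
#' @param classification_args Optional list of arguments passed to
#'   [classify_doses()].
#' @param parallelism Number of worker processes (default 1; uses
#'   `parallel::mclapply` when larger).
#' @return An object of class `sim_metrics`: `summary` (one row per
#'   scenario: selection percentages, mean sample sizes), `selections`
#'   (per-cell selection percentage matrices) and `replicates` (the
#'   per-trial score table).
#' @export
run_study <- function(design, scenarios, n_sims = 100, master_seed = 1,
                      config = trial_config(),
                      classification_args = list(), parallelism = 1) {
  stopifnot(n_sims >= 1)
  if (is.character(scenarios)) scenarios <- load_scenarios(scenarios)
  if (inherits(scenarios, "scenario_spec"))
    scenarios <- stats::setNames(list(scenarios), scenarios$label)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_sims)
  reps <- list()
  selections <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    classification <- do.call(classify_doses,
                              c(list(sc, params = config$utility),
                                classification_args))
    one <- function(r) {
      res <- run_trial(design, sc, config, seed = seeds[r])
      cbind(score_trial(res, classification),
            rec_i = if (is.null(res$recommendation)) NA_integer_
                    else res$recommendation[1],
            rec_j = if (is.null(res$recommendation)) NA_integer_
                    else res$recommendation[2])
    }
    rows <- if (parallelism > 1)
      parallel::mclapply(seq_len(n_sims), one, mc.cores = parallelism)
    else lapply(seq_len(n_sims), one)
    tab <- do.call(rbind, rows)
    tab$scenario <- nm
    tab$replicate <- seq_len(n_sims)
    reps[[nm]] <- tab
    selmat <- matrix(0, sc$grid$I, sc$grid$J)
    sel <- tab[!is.na(tab$rec_i), ]
    for (r in seq_len(nrow(sel)))
      selmat[sel$rec_i[r], sel$rec_j[r]] <-
        selmat[sel$rec_i[r], sel$rec_j[r]] + 1
    selections[[nm]] <- 100 * selmat / n_sims
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  summary <- do.call(rbind, lapply(names(scenarios), function(nm) {
    t <- replicates[replicates$scenario == nm, ]
    cls <- t$selection
    data.frame(scenario = nm, design = class(design)[1],
               n_sims = n_sims,
               pct_correct = 100 * mean(cls == "correct"),
               pct_good = 100 * mean(cls %in% c("correct", "good")),
               pct_acceptable = 100 * mean(cls %in%
                 c("correct", "good", "acceptable")),
               pct_unacceptable = 100 * mean(cls == "unacceptable"),
               pct_none = 100 * mean(cls == "none"),
               mean_n = mean(t$n_patients),
               mean_n_unsafe = mean(t$n_unsafe))
  }))
  structure(list(summary = summary, selections = selections,
                 replicates = replicates, master_seed = master_seed,
                 design = class(design)[1]),
            class = "sim_metrics")
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat(sprintf("sim_metrics [%s], master seed %d\n", x$design,
              x$master_seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Aggregate simulation metrics over scenario groups
#'
#' Computes arithmetic means of the per-scenario metrics over groups of
#' scenarios (e.g. all activity profiles within one toxicity profile,
#' or the grand mean over all 48 combinations).
#'
#' @param metrics A `sim_metrics` (or its `summary` data frame).
#' @param group Either a function mapping scenario names to group
#'   labels, or a character vector of group labels (one per row), or
#'   `NULL` for a single grand mean.
#' @return A data frame of group means.
#' @export
summarize_study <- function(metrics, group = NULL) {
  s <- if (inherits(metrics, "sim_metrics")) metrics$summary else metrics
  labels <- if (is.null(group)) rep("mean", nrow(s))
            else if (is.function(group)) vapply(s$scenario, group, "")
            else group
  stopifnot(length(labels) == nrow(s))
  num <- c("pct_correct", "pct_good", "pct_acceptable",
           "pct_unacceptable", "pct_none", "mean_n", "mean_n_unsafe")
  out <- stats::aggregate(s[num], by = list(group = labels), FUN = mean)
  out
}

#' Export study metrics as tidy CSV / JSON
#'
#' @param metrics A `sim_metrics`.
#' @param csv_file Tidy CSV path (one row per scenario x metric,
#'   `NULL` to skip).
#' @param json_file JSON path (`NULL` to skip).
#' @return Invisibly, the tidy data frame.
#' @export
export_study <- function(metrics, csv_file = NULL, json_file = NULL) {
  s <- metrics$summary
  num <- c("pct_correct", "pct_good", "pct_acceptable",
           "pct_unacceptable", "pct_none", "mean_n", "mean_n_unsafe")
  tidy <- do.call(rbind, lapply(num, function(m)
    data.frame(scenario = s$scenario, design = s$design, metric = m,
               value = s[[m]])))
  if (!is.null(csv_file)) utils::write.csv(tidy, csv_file,
                                           row.names = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(list(summary = s, selections =
                                metrics$selections),
                         json_file, auto_unbox = TRUE, digits = NA)
  invisible(tidy)
}
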