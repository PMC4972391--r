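#' Records restricted to the analysis window
#'
#' Window statistics use the recorded steps with
#' `t >= analysis_window_start` (the last half of a default run); anything
#' earlier is burn-in and never influences them.
#'
#' @param run a [run_simulation()] result.
#' @return The subset of `run$records` inside the window.
#' @export
window_records <- function(run) {
  run$records[run$records$t >= run$config$analysis_window_start, ,
              drop = FALSE]
}

endpoint_strategy_counts <- function(run) {
  live <- run$endpoint$alive
  table(factor(run$endpoint$strategy[live], levels = strategies()))
}

#' Endpoint strategy frequencies across runs
#'
#' For each completed (non-collapsed) run, the frequency of each learning
#' strategy in the final population — the quantity whose across-run
#' distribution summarizes which strategies win. Collapsed runs are dropped
#' with a warning; density estimation over the returned table is left to
#' downstream plotting.
#'
#' @param runs a `run_result` or list of them.
#' @return Data frame with columns `run`, `asocial`, `observational`,
#'   `parental`, `advanced`; one row per completed run, frequencies summing
#'   to 1.
#' @export
endpoint_frequencies <- function(runs) {
  if (inherits(runs, "run_result")) runs <- list(runs)
  ok <- which(!vapply(runs, `[[`, logical(1), "collapsed"))
  empty <- data.frame(run = integer(), asocial = numeric(),
                      observational = numeric(), parental = numeric(),
                      advanced = numeric())
  if (length(ok) < length(runs))
    warning(sprintf("%d collapsed run(s) excluded",
                    length(runs) - length(ok)), call. = FALSE)
  if (length(ok) == 0L) return(empty)
  rows <- lapply(ok, function(i) {
    tab <- endpoint_strategy_counts(runs[[i]])
    fr <- as.numeric(tab) / sum(tab)
    data.frame(run = i, asocial = fr[1], observational = fr[2],
               parental = fr[3], advanced = fr[4])
  })
  do.call(rbind, rows)
}

#' Fraction of window time each strategy spends near fixation
#'
#' A strategy is near fixation at a step when it constitutes at least
#' `threshold` (default 90%) of the population. Returns, per strategy, the
#' fraction of recorded window steps at which that held — the across-time
#' occupancy of the stochastic equilibria.
#'
#' @param run a [run_simulation()] result.
#' @param threshold frequency threshold in (0, 1].
#' @return Named numeric vector over [strategies()], each in `[0, 1]`.
#' @export
near_fixation_fraction <- function(run, threshold = 0.9) {
  w <- window_records(run)
  n_live <- w$n_asocial + w$n_observational + w$n_parental + w$n_advanced
  out <- vapply(strategies(), function(s) {
    if (nrow(w) == 0L) return(NA_real_)
    mean(w[[paste0("n_", s)]] / n_live >= threshold)
  }, numeric(1))
  out
}

#' Window-averaged extrema of the preparedness vector
#'
#' Per run, the time-average over the analysis window of the population
#' maximum (`p_max`) and minimum (`p_min`) preparedness value; then the
#' mean and standard error of those per-run averages across runs. Positive
#' preparedness expresses innate approach of (safe) options, negative
#' preparedness innate avoidance; in runs with preparedness disabled both
#' are identically 0.
#'
#' @param runs a `run_result` or list of them.
#' @return Data frame with columns `stat` (`"p_max"`, `"p_min"`), `mean`,
#'   `se` (across-run standard error), `n_runs`.
#' @export
preparedness_extrema <- function(runs) {
  if (inherits(runs, "run_result")) runs <- list(runs)
  per_max <- vapply(runs, function(r) mean(window_records(r)$p_max),
                    numeric(1))
  per_min <- vapply(runs, function(r) mean(window_records(r)$p_min),
                    numeric(1))
  n <- length(runs)
  se <- function(x) if (n > 1L) sd(x) / sqrt(n) else NA_real_
  data.frame(stat = c("p_max", "p_min"),
             mean = c(mean(per_max), mean(per_min)),
             se = c(se(per_max), se(per_min)),
             n_runs = n)
}

run_window_summary <- function(run) {
  w <- window_records(run)
  n <- run$config$n_agents
  data.frame(foraging_efficiency = mean(w$mean_f),
             danger_death_rate = mean(w$danger_deaths) / n,
             baseline_death_rate = mean(w$baseline_deaths) / n)
}

configs_comparable <- function(a, b) {
  identical(unclass(a$environment), unclass(b$environment)) &&
    identical(unclass(a$learning), unclass(b$learning)) &&
    a$n_agents == b$n_agents && a$n_steps == b$n_steps &&
    a$analysis_window_start == b$analysis_window_start &&
    a$baseline_death_prob == b$baseline_death_prob &&
    identical(a$pure_strategy, b$pure_strategy)
}

#' Foraging-efficiency / death-risk trade-off between matched conditions
#'
#' Compares two collections of runs whose configurations are identical
#' except for `preparedness_enabled`. Foraging efficiency is the
#' window-averaged population mean of per-agent cumulative reward; risk of
#' death is the per-capita per-step probability of dying from a dangerous
#' choice (`danger_deaths / n_agents`, window-averaged); baseline deaths
#' are reported separately. Standard errors are computed across runs.
#'
#' @param runs_with runs with preparedness enabled.
#' @param runs_without matched runs with preparedness disabled.
#' @return Data frame with one row per condition and columns
#'   `condition`, `foraging_efficiency`, `foraging_se`,
#'   `danger_death_rate`, `danger_death_se`, `baseline_death_rate`,
#'   `n_runs`.
#' @export
tradeoff_summary <- function(runs_with, runs_without) {
  if (inherits(runs_with, "run_result")) runs_with <- list(runs_with)
  if (inherits(runs_without, "run_result")) runs_without <- list(runs_without)
  for (r in runs_with)
    if (!isTRUE(r$config$mutation$preparedness_enabled))
      stop("'runs_with' must have preparedness enabled", call. = FALSE)
  for (r in runs_without)
    if (isTRUE(r$config$mutation$preparedness_enabled))
      stop("'runs_without' must have preparedness disabled", call. = FALSE)
  if (!configs_comparable(runs_with[[1]]$config, runs_without[[1]]$config))
    stop("conditions must share all parameters except 'preparedness_enabled'",
         call. = FALSE)
  cond_row <- function(runs, label) {
    s <- do.call(rbind, lapply(runs, run_window_summary))
    n <- nrow(s)
    se <- function(x) if (n > 1L) sd(x) / sqrt(n) else NA_real_
    data.frame(condition = label,
               foraging_efficiency = mean(s$foraging_efficiency),
               foraging_se = se(s$foraging_efficiency),
               danger_death_rate = mean(s$danger_death_rate),
               danger_death_se = se(s$danger_death_rate),
               baseline_death_rate = mean(s$baseline_death_rate),
               n_runs = n)
  }
  rbind(cond_row(runs_with, "with_preparedness"),
        cond_row(runs_without, "without_preparedness"))
}
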