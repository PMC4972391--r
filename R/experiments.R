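#' Specify a replicated experiment sweep
#'
#' Describes a grid of simulation conditions crossed with replicate seeds.
#' Three designs are supported: `mixed` (evolving learning loci, crossing
#' danger levels, reward-change rates and the two preparedness
#' conditions), `pure_strategy` (additionally crossed with the four
#' locked learning strategies), and `novel_danger` (danger fixed at one
#' option with `p_newdanger = 0.001`, crossing change rates and
#' preparedness). The default change-rate grid covers stationary (0),
#' between-generation (0.005) and within-generation (0.05) stochasticity.
#'
#' @param danger_levels integer vector of danger counts.
#' @param p_change_levels numeric vector of reward-change probabilities.
#' @param preparedness_conditions logical vector of preparedness settings.
#' @param replicates replicate runs per cell.
#' @param base_seed integer; replicate seeds are derived deterministically
#'   from it (keep it small — derived seeds stay below base_seed +
#'   cells x replicates).
#' @param design one of `"mixed"`, `"pure_strategy"`, `"novel_danger"`.
#' @param n_steps,n_agents,record_every forwarded to [sim_config()].
#' @param p_danger probability of a fatal outcome on a dangerous choice.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(danger_levels = 0:7,
                       p_change_levels = c(0, 0.005, 0.05),
                       preparedness_conditions = c(TRUE, FALSE),
                       replicates = 100L, base_seed = 1L,
                       design = c("mixed", "pure_strategy", "novel_danger"),
                       n_steps = 50000L, n_agents = 100L,
                       record_every = 1L, p_danger = 0.5) {
  design <- match.arg(design)
  if (length(danger_levels) == 0L || length(p_change_levels) == 0L ||
      length(preparedness_conditions) == 0L)
    stop("level lists must be non-empty", call. = FALSE)
  if (replicates < 1L)
    stop("'replicates' must be at least 1", call. = FALSE)
  structure(list(danger_levels = as.integer(danger_levels),
                 p_change_levels = as.numeric(p_change_levels),
                 preparedness_conditions = as.logical(preparedness_conditions),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), design = design,
                 n_steps = as.integer(n_steps),
                 n_agents = as.integer(n_agents),
                 record_every = as.integer(record_every),
                 p_danger = p_danger),
            class = "sweep_spec")
}

cell_label <- function(design, danger, p_change, prep, strategy = NULL) {
  base <- if (design == "novel_danger")
    sprintf("nd_c%s_prep%d", format(p_change, scientific = FALSE),
            as.integer(prep))
  else
    sprintf("d%d_c%s_prep%d", danger, format(p_change, scientific = FALSE),
            as.integer(prep))
  if (!is.null(strategy)) base <- paste0(base, "_", strategy)
  base
}

#' Expand a sweep into concrete simulation configurations
#'
#' Builds the Cartesian product of the spec's levels and replicates.
#' Replicate `r` of cell `i` receives seed
#' `base_seed + (i - 1) * replicates + (r - 1)`, which is deterministic
#' and collision-free across the whole experiment. Each returned
#' [sim_config()] additionally carries `cell` (condition label) and
#' `replicate` fields.
#'
#' @param spec a [sweep_spec()].
#' @return List of `sim_config` objects.
#' @export
expand_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  cells <- switch(spec$design,
    mixed = expand.grid(danger = spec$danger_levels,
                        p_change = spec$p_change_levels,
                        prep = spec$preparedness_conditions,
                        stringsAsFactors = FALSE),
    pure_strategy = expand.grid(danger = spec$danger_levels,
                                p_change = spec$p_change_levels,
                                prep = spec$preparedness_conditions,
                                strategy = strategies(),
                                stringsAsFactors = FALSE),
    novel_danger = expand.grid(danger = 1L,
                               p_change = spec$p_change_levels,
                               prep = spec$preparedness_conditions,
                               stringsAsFactors = FALSE))
  configs <- vector("list", nrow(cells) * spec$replicates)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    danger <- cells$danger[i]
    p_change <- cells$p_change[i]
    prep <- cells$prep[i]
    strategy <- if (spec$design == "pure_strategy")
      as.character(cells$strategy[i]) else NULL
    p_newdanger <- if (spec$design == "novel_danger") 0.001 else 0
    label <- cell_label(spec$design, danger, p_change, prep, strategy)
    for (r in seq_len(spec$replicates)) {
      k <- k + 1L
      cfg <- sim_config(
        n_agents = spec$n_agents, n_steps = spec$n_steps,
        environment = env_config(p_change = p_change,
                                 danger_count = danger,
                                 p_danger = spec$p_danger,
                                 p_newdanger = p_newdanger),
        mutation = mutation_config(preparedness_enabled = prep),
        pure_strategy = strategy,
        seed = spec$base_seed + (i - 1L) * spec$replicates + (r - 1L),
        record_every = spec$record_every)
      cfg$cell <- label
      cfg$replicate <- r
      configs[[k]] <- cfg
    }
  }
  configs
}

#' Run a full experiment sweep
#'
#' Executes every cell x replicate of the expanded sweep, streaming each
#' run's per-step records to `runs/<cell>/<replicate>.csv` and its summary
#' to `runs/<cell>/<replicate>.json` under `out_dir`. Completed runs
#' (detected by their files) are skipped, so interrupted experiments
#' resume without recomputation; because every run is seeded
#' deterministically, resumed and uninterrupted experiments produce
#' identical output. Collapsed runs are logged with a warning and their
#' files are still written. Aggregate tables are then rebuilt from the
#' on-disk runs by [summarize_experiment()].
#'
#' @param spec a [sweep_spec()].
#' @param out_dir output directory.
#' @param parallelism accepted for interface compatibility; runs share no
#'   state so they may be executed concurrently, but this implementation
#'   executes them sequentially.
#' @param quiet suppress per-run progress messages.
#' @return Invisibly, the aggregate tables from [summarize_experiment()].
#' @export
run_experiment <- function(spec, out_dir, parallelism = 1L, quiet = TRUE) {
  configs <- expand_sweep(spec)
  for (cfg in configs) {
    csv <- file.path(out_dir, "runs", cfg$cell,
                     sprintf("%04d.csv", cfg$replicate))
    json <- file.path(out_dir, "runs", cfg$cell,
                      sprintf("%04d.json", cfg$replicate))
    if (file.exists(csv) && file.exists(json)) next
    run <- run_simulation(cfg)
    if (run$collapsed)
      warning(sprintf("run %s/%d collapsed at step %d", cfg$cell,
                      cfg$replicate,
                      if (nrow(run$records)) max(run$records$t) + 1L else 1L),
              call. = FALSE)
    write_run_result(run, csv, json)
    if (!quiet)
      message(sprintf("completed %s replicate %d", cfg$cell, cfg$replicate))
  }
  invisible(summarize_experiment(out_dir))
}

#' Aggregate an experiment directory
#'
#' Recomputes all cross-run aggregate tables from the per-run CSV/JSON
#' files on disk (so aggregation is independent of whether the runs were
#' produced in one session or resumed): endpoint strategy frequencies,
#' near-fixation occupancy, window-averaged preparedness extrema, and the
#' foraging/death trade-off between matched preparedness conditions.
#' Tables are written under `aggregate/` and returned.
#'
#' @param out_dir an experiment directory written by [run_experiment()].
#' @return Named list of data frames (`endpoint_frequencies`,
#'   `near_fixation`, `preparedness_extrema`, `tradeoff`).
#' @export
summarize_experiment <- function(out_dir) {
  runs_dir <- file.path(out_dir, "runs")
  cells <- sort(list.dirs(runs_dir, recursive = FALSE, full.names = FALSE))
  ep_rows <- list(); nf_rows <- list(); px_rows <- list(); tr_rows <- list()
  cell_stats <- list()
  for (cell in cells) {
    jsons <- sort(list.files(file.path(runs_dir, cell), pattern = "\\.json$",
                             full.names = TRUE))
    per_run <- list()
    for (jp in jsons) {
      s <- read_run_summary(jp)
      rec <- read_run_records(sub("\\.json$", ".csv", jp))
      ws <- s$config$analysis_window_start
      n_agents <- s$config$n_agents
      w <- rec[rec$t >= ws, , drop = FALSE]
      rep_id <- as.integer(sub("\\.json$", "", basename(jp)))
      counts <- unlist(s$endpoint$strategy_counts)[strategies()]
      freqs <- counts / sum(counts)
      ep_rows[[length(ep_rows) + 1L]] <- data.frame(
        cell = cell, replicate = rep_id, collapsed = isTRUE(s$collapsed),
        asocial = freqs[["asocial"]],
        observational = freqs[["observational"]],
        parental = freqs[["parental"]], advanced = freqs[["advanced"]])
      n_live <- w$n_asocial + w$n_observational + w$n_parental + w$n_advanced
      nf <- vapply(strategies(), function(st)
        if (nrow(w)) mean(w[[paste0("n_", st)]] / n_live >= 0.9)
        else NA_real_, numeric(1))
      nf_rows[[length(nf_rows) + 1L]] <- data.frame(
        cell = cell, replicate = rep_id, asocial = nf[["asocial"]],
        observational = nf[["observational"]],
        parental = nf[["parental"]], advanced = nf[["advanced"]])
      per_run[[length(per_run) + 1L]] <- data.frame(
        p_max = mean(w$p_max), p_min = mean(w$p_min),
        foraging_efficiency = mean(w$mean_f),
        danger_death_rate = mean(w$danger_deaths) / n_agents,
        baseline_death_rate = mean(w$baseline_deaths) / n_agents)
    }
    if (length(per_run) == 0L) next
    pr <- do.call(rbind, per_run)
    n <- nrow(pr)
    se <- function(x) if (n > 1L) sd(x) / sqrt(n) else NA_real_
    px_rows[[length(px_rows) + 1L]] <- data.frame(
      cell = cell, n_runs = n,
      p_max_mean = mean(pr$p_max), p_max_se = se(pr$p_max),
      p_min_mean = mean(pr$p_min), p_min_se = se(pr$p_min))
    cell_stats[[cell]] <- data.frame(
      cell = cell, n_runs = n,
      foraging_efficiency = mean(pr$foraging_efficiency),
      foraging_se = se(pr$foraging_efficiency),
      danger_death_rate = mean(pr$danger_death_rate),
      danger_death_se = se(pr$danger_death_rate),
      baseline_death_rate = mean(pr$baseline_death_rate))
  }
  # trade-off: pair cells that differ only in the preparedness flag
  for (cell in names(cell_stats)) {
    if (!grepl("prep1", cell, fixed = TRUE)) next
    partner <- sub("prep1", "prep0", cell, fixed = TRUE)
    if (!partner %in% names(cell_stats)) next
    a <- cell_stats[[cell]]; b <- cell_stats[[partner]]
    tr_rows[[length(tr_rows) + 1L]] <- data.frame(
      cell = sub("_prep1", "", cell, fixed = TRUE),
      foraging_with = a$foraging_efficiency,
      foraging_without = b$foraging_efficiency,
      danger_death_with = a$danger_death_rate,
      danger_death_without = b$danger_death_rate,
      baseline_death_with = a$baseline_death_rate,
      baseline_death_without = b$baseline_death_rate)
  }
  bind <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  agg <- list(
    endpoint_frequencies = bind(ep_rows, data.frame()),
    near_fixation = bind(nf_rows, data.frame()),
    preparedness_extrema = bind(px_rows, data.frame()),
    tradeoff = bind(tr_rows, data.frame()))
  agg_dir <- file.path(out_dir, "aggregate")
  dir.create(agg_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(agg))
    write.csv(agg[[nm]], file.path(agg_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  agg
}
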