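# Serialization of run results: per-step records as CSV, run summary as
# JSON (config echo, seed, collapse flag, endpoint strategy counts and
# preparedness statistics).

config_as_list <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

#' Write a run result to disk
#'
#' Writes the per-step metrics table as CSV (one row per recorded step,
#' fixed column set, see [run_simulation()]) and a JSON summary holding
#' the configuration echo, seed, collapse flag, endpoint strategy counts
#' and endpoint preparedness statistics. Output is byte-deterministic for
#' a given run.
#'
#' @param run a [run_simulation()] result.
#' @param csv_path,json_path output file paths (directories are created).
#' @return Invisibly, the two paths.
#' @export
write_run_result <- function(run, csv_path, json_path) {
  for (p in c(csv_path, json_path))
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  write.csv(run$records, csv_path, row.names = FALSE)
  live <- run$endpoint$alive
  prep <- run$endpoint$preparedness[live, , drop = FALSE]
  counts <- as.list(endpoint_strategy_counts(run))
  summary <- list(
    seed = run$config$seed,
    collapsed = run$collapsed,
    steps_completed = if (nrow(run$records) > 0L)
      max(run$records$t) else 0L,
    endpoint = list(
      strategy_counts = counts,
      preparedness = list(max = if (length(prep)) max(prep) else 0,
                          min = if (length(prep)) min(prep) else 0,
                          mean = if (length(prep)) mean(prep) else 0)),
    config = config_as_list(run$config))
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}

#' Read a run's per-step records back from CSV
#'
#' @param csv_path path written by [write_run_result()].
#' @return Data frame of per-step records.
#' @export
read_run_records <- function(csv_path) {
  read.csv(csv_path)
}

#' Read a run's JSON summary back
#'
#' @param json_path path written by [write_run_result()].
#' @return The summary list.
#' @export
read_run_summary <- function(json_path) {
  jsonlite::read_json(json_path, simplifyVector = TRUE)
}
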