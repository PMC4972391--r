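test_that("sweep expansion produces the full condition grid with unique seeds", {
  full <- sweep_spec()
  cfgs <- expand_sweep(full)
  expect_length(cfgs, 8 * 3 * 2 * 100)
  seeds <- vapply(cfgs, `[[`, integer(1), "seed")
  expect_length(unique(seeds), length(cfgs))

  pure <- sweep_spec(danger_levels = c(0, 4), p_change_levels = 0.05,
                     replicates = 10, design = "pure_strategy")
  pcfg <- expand_sweep(pure)
  expect_length(pcfg, 160)
  expect_setequal(unique(vapply(pcfg, `[[`, character(1), "pure_strategy")),
                  strategies())

  nd <- expand_sweep(sweep_spec(design = "novel_danger", replicates = 2))
  expect_true(all(vapply(nd, function(c) c$environment$danger_count,
                         integer(1)) == 1L))
  expect_true(all(vapply(nd, function(c) c$environment$p_newdanger,
                         numeric(1)) == 0.001))

  # deterministic: re-expansion assigns identical seeds and cells
  again <- expand_sweep(full)
  expect_identical(vapply(again, `[[`, integer(1), "seed"), seeds)
  expect_identical(vapply(again, `[[`, character(1), "cell"),
                   vapply(cfgs, `[[`, character(1), "cell"))

  expect_error(expand_sweep(sweep_spec(danger_levels = integer(0))),
               "non-empty")
})

test_that("experiments run, resume, and aggregate deterministically", {
  spec <- sweep_spec(danger_levels = c(0, 2), p_change_levels = 0.05,
                     preparedness_conditions = c(TRUE, FALSE),
                     replicates = 2, base_seed = 3, n_steps = 300,
                     n_agents = 30)
  dirA <- file.path(tempdir(), "expA")
  unlink(dirA, recursive = TRUE)
  aggA <- run_experiment(spec, dirA)
  csvs <- list.files(file.path(dirA, "runs"), recursive = TRUE,
                     pattern = "\\.csv$", full.names = TRUE)
  expect_length(csvs, 8)
  md5_before <- tools::md5sum(csvs)

  # a second invocation recomputes nothing and reproduces the aggregates
  aggA2 <- run_experiment(spec, dirA)
  expect_identical(tools::md5sum(csvs), md5_before)
  expect_identical(aggA, aggA2)

  # interrupt-and-resume: seed a fresh directory with a subset of the
  # completed runs, rerun, and compare aggregate bytes
  dirB <- file.path(tempdir(), "expB")
  unlink(dirB, recursive = TRUE)
  first_cell <- list.dirs(file.path(dirA, "runs"),
                          recursive = FALSE)[1]
  dir.create(file.path(dirB, "runs"), recursive = TRUE)
  file.copy(first_cell, file.path(dirB, "runs"), recursive = TRUE)
  run_experiment(spec, dirB)
  for (f in c("endpoint_frequencies.csv", "near_fixation.csv",
              "preparedness_extrema.csv", "tradeoff.csv")) {
    expect_identical(readLines(file.path(dirB, "aggregate", f)),
                     readLines(file.path(dirA, "aggregate", f)))
  }
  unlink(c(dirA, dirB), recursive = TRUE)
})

test_that("aggregates recomputed from streamed CSVs match in-memory metrics", {
  spec <- sweep_spec(danger_levels = 2, p_change_levels = 0.05,
                     preparedness_conditions = c(TRUE, FALSE),
                     replicates = 3, base_seed = 11, n_steps = 300,
                     n_agents = 30)
  dirC <- file.path(tempdir(), "expC")
  unlink(dirC, recursive = TRUE)
  agg <- run_experiment(spec, dirC)

  cfgs <- expand_sweep(spec)
  runs <- lapply(cfgs, run_simulation)
  cells <- vapply(cfgs, `[[`, character(1), "cell")
  w_runs <- runs[cells == "d2_c0.05_prep1"]
  o_runs <- runs[cells == "d2_c0.05_prep0"]

  ef_mem <- endpoint_frequencies(w_runs)
  ef_disk <- agg$endpoint_frequencies
  ef_disk <- ef_disk[ef_disk$cell == "d2_c0.05_prep1", ]
  expect_equal(ef_disk[, strategies()], ef_mem[, strategies()],
               tolerance = 1e-9, ignore_attr = TRUE)

  px_mem <- preparedness_extrema(w_runs)
  px_disk <- agg$preparedness_extrema
  px_disk <- px_disk[px_disk$cell == "d2_c0.05_prep1", ]
  expect_equal(c(px_disk$p_max_mean, px_disk$p_min_mean), px_mem$mean,
               tolerance = 1e-9)

  ts_mem <- tradeoff_summary(w_runs, o_runs)
  ts_disk <- agg$tradeoff
  expect_equal(ts_disk$foraging_with, ts_mem$foraging_efficiency[1],
               tolerance = 1e-9)
  expect_equal(ts_disk$foraging_without, ts_mem$foraging_efficiency[2],
               tolerance = 1e-9)
  expect_equal(ts_disk$danger_death_with, ts_mem$danger_death_rate[1],
               tolerance = 1e-9)

  nf_mem <- t(vapply(w_runs, near_fixation_fraction, numeric(4)))
  nf_disk <- agg$near_fixation
  nf_disk <- nf_disk[nf_disk$cell == "d2_c0.05_prep1", ]
  expect_equal(as.matrix(nf_disk[, strategies()]), nf_mem,
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(dirC, recursive = TRUE)
})

test_that("run results round-trip through their CSV and JSON files", {
  run <- run_simulation(tiny_sim(n_agents = 25L, n_steps = 150L, seed = 8L,
                                 environment = env_config(danger_count = 2)))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_run_result(run, csv, json)
  rec <- read_run_records(csv)
  expect_equal(rec, run$records, tolerance = 1e-12)
  s <- read_run_summary(json)
  expect_false(s$collapsed)
  expect_identical(s$seed, 8L)
  expect_identical(unlist(s$endpoint$strategy_counts)[["asocial"]],
                   sum(run$endpoint$strategy[run$endpoint$alive] ==
                         "asocial"))
  expect_identical(s$config$n_agents, 25L)
  unlink(c(csv, json))
})
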