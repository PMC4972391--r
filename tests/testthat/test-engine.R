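test_that("reproduction weights order the population by foraging efficiency", {
  expect_equal(reproduction_probabilities(c(10, 20, 5)), c(0.5, 1.0, 0.25))
  expect_equal(reproduction_probabilities(c(7, 7, 7)), c(1, 1, 1))
  expect_equal(reproduction_probabilities(c(0, 0)), c(1, 1))
  expect_error(reproduction_probabilities(numeric(0)), "collapsed")
})

test_that("replenishment fills exactly the vacancies from the survivors", {
  cfg <- sim_config(n_agents = 100L, n_steps = 1L,
                    mutation = mutation_config(event_prob = 0))
  founder <- make_founder()
  q0 <- rep(10, 10)
  agents <- replicate(100, list(q_values = q0, cumulative_reward = 5,
                                genotype = founder, alive = TRUE, age = 3L),
                      simplify = FALSE)
  # no vacancies: input returned unchanged, no reproduction
  expect_identical(replenish(agents, rep(1, 100), cfg), agents)

  # one survivor with weight 1 parents all 99 offspring
  set.seed(41)
  one <- agents[1]
  one[[1]]$genotype$preparedness[1] <- 7
  out <- replenish(one, 1, cfg)
  expect_length(out, 100)
  expect_true(all(vapply(out, function(a) a$genotype$preparedness[1],
                         numeric(1)) == 7))
  expect_true(all(vapply(out[-1], `[[`, numeric(1),
                         "cumulative_reward") == 0))
  expect_error(replenish(list(), rep(1, 0), cfg), "collapsed")
})

test_that("offspring counts follow the cyclic-Bernoulli scheme in expectation", {
  # two survivors with weights 1.0 and 0.5 filling two vacancies; exact
  # enumeration of the single-shuffle cyclic scheme: with order (A,B) the
  # counts are (1,1) or (2,0) each w.p. 1/2; with order (B,A) they are
  # (1,1) w.p. 3/4 and (2,0) w.p. 1/4; hence E[A] = 1.375, E[B] = 0.625
  set.seed(42)
  cfg <- sim_config(n_agents = 4L, n_steps = 1L,
                    mutation = mutation_config(event_prob = 0))
  gA <- make_founder(); gA$preparedness[1] <- 1
  gB <- make_founder(); gB$preparedness[1] <- 2
  q0 <- rep(10, 10)
  survivors <- list(
    list(q_values = q0, cumulative_reward = 20, genotype = gA,
         alive = TRUE, age = 1L),
    list(q_values = q0, cumulative_reward = 10, genotype = gB,
         alive = TRUE, age = 1L))
  w <- reproduction_probabilities(c(20, 10))
  expect_equal(w, c(1, 0.5))
  n_rep <- 10000
  countA <- integer(n_rep)
  for (i in seq_len(n_rep)) {
    out <- replenish(survivors, w, cfg)
    marks <- vapply(out[3:4], function(a) a$genotype$preparedness[1],
                    numeric(1))
    countA[i] <- sum(marks == 1)
  }
  # sd of A-count is sqrt(0.375 * 0.625)
  se <- sqrt(0.375 * 0.625 / n_rep)
  expect_lt(abs(mean(countA) - 1.375), 3 * se)
})

test_that("a fatal observed outcome drops the observer's value by alpha * (fatal - Q)", {
  set.seed(43)
  cfg <- sim_config(n_agents = 2L, n_steps = 1L, baseline_death_prob = 0,
                    environment = env_config(danger_count = 1, p_danger = 1),
                    mutation = mutation_config(event_prob = 0))
  # victim innately drawn to the dangerous option; observer repelled by it
  env <- structure(list(rewards = as.integer(c(5, 8, 12, rep(10, 7))),
                        dangerous = 1L), class = "env_state")
  g_victim <- genotype(preparedness = c(1000, rep(0, 9)))
  g_obs <- genotype(preparedness = c(-1000, rep(0, 9)), obs_allele = 1L)
  q0 <- rep(10, 10)
  state <- list(t = 0L, agents = list(
    list(q_values = q0, cumulative_reward = 0, genotype = g_victim,
         alive = TRUE, age = 0L),
    list(q_values = q0, cumulative_reward = 0, genotype = g_obs,
         alive = TRUE, age = 0L)), env = env, collapsed = FALSE)
  out <- time_step(state, cfg)
  d <- attr(out, "diagnostics")
  expect_identical(d$danger_deaths, 1L)
  expect_identical(d$births, 1L)
  expect_length(out$agents, 2)
  # survivor is first; its value for the observed option is
  # 10 + 0.3 * (-1000 - 10) = -293
  expect_equal(out$agents[[1]]$q_values[1], -293)
  expect_identical(out$agents[[1]]$genotype$obs_allele, 1L)
})

test_that("the population returns to size n at every step boundary", {
  set.seed(44)
  cfg <- sim_config(n_agents = 50L, n_steps = 100L,
                    environment = env_config(danger_count = 3,
                                             p_change = 0.05))
  state <- init_run_state(cfg)
  for (s in 1:100) {
    state <- time_step(state, cfg)
    d <- attr(state, "diagnostics")
    expect_length(state$agents, 50)
    expect_identical(d$births, d$danger_deaths + d$baseline_deaths)
  }
})

test_that("without deaths the population composition is frozen", {
  set.seed(45)
  cfg <- sim_config(n_agents = 20L, n_steps = 1L, baseline_death_prob = 0,
                    environment = env_config(danger_count = 0))
  state <- init_run_state(cfg)
  for (s in 1:20) {
    state <- time_step(state, cfg)
    expect_identical(attr(state, "diagnostics")$births, 0L)
    expect_length(state$agents, 20)
    expect_true(all(vapply(state$agents, function(a)
      identical(a$genotype, make_founder()), logical(1))))
  }
})

test_that("cumulative reward equals the sum of own realized rewards", {
  set.seed(46)
  cfg <- sim_config(n_agents = 12L, n_steps = 60L,
                    environment = env_config(danger_count = 2,
                                             p_change = 0.05))
  state <- init_run_state(cfg)
  ledger <- numeric(12)
  for (s in 1:60) {
    state <- time_step(state, cfg)
    d <- attr(state, "diagnostics")
    rewards <- vapply(d$outcomes, `[[`, numeric(1), "reward")
    ledger <- c(ledger[d$survivor_index] + rewards[d$survivor_index],
                numeric(d$births))
    expect_equal(vapply(state$agents, `[[`, numeric(1),
                        "cumulative_reward"), ledger)
    # newborns have not acted in their birth step
    if (d$births > 0) {
      born <- state$agents[seq(13 - d$births, 12)]
      expect_true(all(vapply(born, `[[`, integer(1), "age") == 0L))
      expect_true(all(vapply(born, `[[`, numeric(1),
                             "cumulative_reward") == 0))
    }
  }
})

test_that("full runs are reproducible bit-for-bit from the seed", {
  cfg <- tiny_sim(n_agents = 30L, n_steps = 500L, seed = 99L,
                  environment = env_config(danger_count = 2,
                                           p_change = 0.05))
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1, r2)
  r3 <- run_simulation(tiny_sim(n_agents = 30L, n_steps = 500L, seed = 100L,
                                environment = env_config(danger_count = 2,
                                                         p_change = 0.05)))
  expect_false(identical(r1$records, r3$records))
})

test_that("a zero-step run returns the founder population", {
  run <- run_simulation(tiny_sim(n_steps = 0L, analysis_window_start = 1L))
  expect_identical(nrow(run$records), 0L)
  expect_false(run$collapsed)
  expect_true(all(run$endpoint$strategy == "asocial"))
  expect_true(all(run$endpoint$q_values == 10))
  expect_true(all(run$endpoint$preparedness == 0))
  expect_true(all(run$endpoint$cumulative_reward == 0))
})

test_that("overwhelming danger collapses the run gracefully", {
  # nine lethal options that relocate every step: learned safety goes
  # stale immediately, so the population cannot persist
  run <- run_simulation(sim_config(
    n_agents = 5L, n_steps = 200L, seed = 5L,
    environment = env_config(danger_count = 9, p_danger = 1,
                             p_newdanger = 1)))
  expect_true(run$collapsed)
  expect_lt(nrow(run$records), 200)
  expect_false(any(run$endpoint$alive))

  # the R-level scheduler refuses to advance a collapsed state
  state <- list(t = 3L, agents = list(), env = NULL, collapsed = TRUE)
  expect_error(time_step(state, sim_config()), "collapsed")
})

test_that("pure-strategy runs keep every agent on the locked strategy", {
  for (s in c("asocial", "advanced")) {
    run <- run_simulation(sim_config(
      n_agents = 40L, n_steps = 400L, seed = 7L, pure_strategy = s,
      environment = env_config(danger_count = 2, p_change = 0.05)))
    live <- run$endpoint$alive
    expect_true(all(run$endpoint$strategy[live] == s))
    counts <- run$records[, paste0("n_", strategies())]
    expect_true(all(counts[[paste0("n_", s)]] == 40))
  }
})
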