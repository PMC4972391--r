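#' Simulation configuration
#'
#' Bundles every parameter of a run: population size, run length, the
#' analysis window, the environment, learning and mutation parameters, the
#' per-step baseline death probability, an optional pure-strategy lock, and
#' the RNG seed. Defaults reproduce the main study conditions: 100 haploid
#' asexually reproducing agents, 50000 time-steps with analyses on the last
#' 25000, baseline mortality 0.02 per agent per step.
#'
#' @param n_agents fixed population size.
#' @param n_steps number of time-steps.
#' @param analysis_window_start first step index included in window
#'   statistics; defaults to `n_steps / 2`.
#' @param environment an [env_config()].
#' @param learning a [learning_params()].
#' @param mutation a [mutation_config()].
#' @param baseline_death_prob per-agent per-step probability of death
#'   unrelated to danger.
#' @param pure_strategy `NULL` for evolving learning loci, or one of
#'   [strategies()] to lock every agent (founders and offspring) to that
#'   strategy, with learning-locus mutations silenced.
#' @param seed integer seed; `run_simulation` calls `set.seed(seed)` so a
#'   run is fully reproducible.
#' @param record_every record a step row every this many steps (1 = every
#'   step). Window metrics are robust to thinning.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_agents = 100L, n_steps = 50000L,
                       analysis_window_start = NULL,
                       environment = env_config(),
                       learning = learning_params(),
                       mutation = mutation_config(),
                       baseline_death_prob = 0.02,
                       pure_strategy = NULL,
                       seed = 1L,
                       record_every = 1L) {
  n_agents <- as.integer(n_agents)
  n_steps <- as.integer(n_steps)
  if (is.null(analysis_window_start))
    analysis_window_start <- max(1L, n_steps %/% 2L)
  analysis_window_start <- as.integer(analysis_window_start)
  if (n_agents <= 0L) stop("'n_agents' must be positive", call. = FALSE)
  if (n_steps < 0L) stop("'n_steps' must be non-negative", call. = FALSE)
  if (n_steps > 0L && analysis_window_start > n_steps)
    stop("'analysis_window_start' must not exceed 'n_steps'", call. = FALSE)
  if (baseline_death_prob < 0 || baseline_death_prob > 1)
    stop("'baseline_death_prob' must be in [0, 1]", call. = FALSE)
  if (!is.null(pure_strategy) &&
      !(is.character(pure_strategy) && length(pure_strategy) == 1L &&
        pure_strategy %in% strategies()))
    stop("'pure_strategy' must be NULL or one of strategies()",
         call. = FALSE)
  stopifnot(inherits(environment, "env_config"),
            inherits(learning, "learning_params"),
            inherits(mutation, "mutation_config"))
  structure(list(n_agents = n_agents, n_steps = n_steps,
                 analysis_window_start = analysis_window_start,
                 environment = environment, learning = learning,
                 mutation = mutation,
                 baseline_death_prob = baseline_death_prob,
                 pure_strategy = pure_strategy,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' Fitness-proportional reproduction weights
#'
#' Each living agent's probability of reproducing per visit is its
#' cumulative reward divided by the population maximum, giving a
#' probabilistic ordering by foraging efficiency (the fittest agent always
#' has weight 1). When every agent's cumulative reward is 0 — possible
#' right after initialization — all weights are set equal (1) so early
#' reproduction is unbiased rather than impossible.
#'
#' @param fitness numeric vector of living agents' cumulative rewards.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
reproduction_probabilities <- function(fitness) {
  if (length(fitness) == 0L)
    stop("population collapsed: no living agents", call. = FALSE)
  m <- max(fitness)
  if (m <= 0) rep(1, length(fitness)) else fitness / m
}

# internal agent constructor (plain list; kept light for the R-level engine)
new_agent <- function(genotype, q_values) {
  list(q_values = q_values, cumulative_reward = 0, genotype = genotype,
       alive = TRUE, age = 0L)
}

#' Replenish the population by probabilistic reproduction
#'
#' The survivors are shuffled once into a random order, then visited
#' cyclically; on each visit the agent produces one offspring with
#' probability equal to its reproduction weight, until the population is
#' back at `n_agents`. Offspring inherit the parent's genotype passed
#' through [mutate()], receive initial expected values via
#' [initial_q_values()] (a copy of the parent's values for `T1` carriers),
#' start with zero cumulative reward and age 0, and do not act or reproduce
#' until the next time-step. If there are no vacancies no reproduction
#' occurs and the input is returned unchanged. If every survivor's weight
#' is 0 (the maximum-fitness agent died of baseline mortality and all
#' remaining fitness is 0) the weights fall back to all-equal, mirroring
#' the all-zero-fitness rule.
#'
#' @param agents list of living agents.
#' @param weights reproduction weights aligned with `agents` (from
#'   [reproduction_probabilities()], computed before baseline mortality).
#' @param config a [sim_config()].
#' @return List of agents of length `config$n_agents` (survivors first,
#'   then offspring in birth order).
#' @export
replenish <- function(agents, weights, config) {
  n_alive <- length(agents)
  if (n_alive == 0L)
    stop("population collapsed: no living agents", call. = FALSE)
  vacancies <- config$n_agents - n_alive
  if (vacancies <= 0L)
    return(agents)
  if (max(weights) <= 0) weights[] <- 1
  ord <- sample.int(n_alive)
  lock <- !is.null(config$pure_strategy)
  offspring <- vector("list", vacancies)
  born <- 0L
  pos <- 1L
  while (born < vacancies) {
    p <- ord[pos]
    pos <- pos %% n_alive + 1L
    if (runif(1) < weights[p]) {
      parent <- agents[[p]]
      g <- mutate(parent$genotype, config$mutation, lock_strategy = lock)
      q <- initial_q_values(parent, g, config$learning,
                            config$environment$n_options)
      born <- born + 1L
      offspring[[born]] <- new_agent(g, q)
    }
  }
  c(agents, offspring)
}

#' Initialize a run state
#'
#' Builds the founder population (all-[make_founder()] genotypes, or the
#' locked pure-strategy genotype) with every expected value at `q_init`,
#' and an initialized environment.
#'
#' @param config a [sim_config()].
#' @return A list with elements `t` (0), `agents`, `env`, `collapsed`.
#' @export
init_run_state <- function(config) {
  g <- make_founder(config$environment$n_options)
  if (!is.null(config$pure_strategy)) {
    g$obs_allele <- as.integer(config$pure_strategy %in%
                                 c("observational", "advanced"))
    g$par_allele <- as.integer(config$pure_strategy %in%
                                 c("parental", "advanced"))
  }
  q0 <- rep(config$learning$q_init, config$environment$n_options)
  agents <- replicate(config$n_agents, new_agent(g, q0), simplify = FALSE)
  list(t = 0L, agents = agents, env = init_environment(config$environment),
       collapsed = FALSE)
}

#' Execute one scheduled time-step
#'
#' Runs the per-step event sequence: (i) reward drift (and danger
#' reassignment when `p_newdanger > 0`); (ii) every living agent draws a
#' choice from the softmax over `Q + P` and its outcome is resolved; (iii)
#' every observational learner updates from the outcome of one other
#' uniformly chosen agent (fatal outcomes included — observing deaths is
#' the point); (iv) agents with fatal outcomes are removed; (v) survivors
#' update their own chosen option and add the reward to cumulative fitness;
#' (vi) reproduction weights are computed over the survivors; (vii) each
#' survivor dies with the baseline probability (weights are not
#' recomputed); (viii) the population is replenished by [replenish()].
#' Newborns never act, observe, or die within their birth step.
#'
#' This R implementation defines the semantics operation by operation and
#' is used directly for small populations; [run_simulation()] executes the
#' same schedule in compiled code.
#'
#' @param state a state from [init_run_state()] or a previous `time_step`.
#' @param config a [sim_config()].
#' @return The updated state, with a `diagnostics` attribute (list with
#'   `outcomes`, `danger_deaths`, `baseline_deaths`, `births`).
#' @export
time_step <- function(state, config) {
  if (isTRUE(state$collapsed))
    stop("run has collapsed; no further steps possible", call. = FALSE)
  ecfg <- config$environment
  env <- step_rewards(state$env, ecfg)
  env <- step_danger(env, ecfg)
  agents <- state$agents
  n <- length(agents)

  # (ii) every living agent chooses and its outcome is resolved
  outcomes <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- choice_probabilities(agents[[i]]$q_values,
                               agents[[i]]$genotype$preparedness)
    outcomes[[i]] <- resolve_outcome(env, sample_choice(pr), ecfg)
  }

  # (iii) observational learners update from one other agent's outcome
  if (n > 1L) {
    for (i in seq_len(n)) {
      if (agents[[i]]$genotype$obs_allele == 1L) {
        others <- seq_len(n)[-i]
        tgt <- others[sample.int(n - 1L, 1L)]
        r <- vicarious_reinforcement(outcomes[[tgt]], config$learning)
        agents[[i]]$q_values <- rw_update(agents[[i]]$q_values,
                                          outcomes[[tgt]]$option, r,
                                          config$learning$alpha)$q_values
      }
    }
  }

  # (iv) fatal outcomes remove agents before their own update
  fatal <- vapply(outcomes, `[[`, logical(1), "fatal")
  danger_deaths <- sum(fatal)

  # (v) survivors learn from, and bank, their own reward
  for (i in which(!fatal)) {
    o <- outcomes[[i]]
    agents[[i]]$q_values <- rw_update(agents[[i]]$q_values, o$option,
                                      o$reward,
                                      config$learning$alpha)$q_values
    agents[[i]]$cumulative_reward <- agents[[i]]$cumulative_reward + o$reward
    agents[[i]]$age <- agents[[i]]$age + 1L
  }
  survivors <- agents[!fatal]
  if (length(survivors) == 0L) {
    state$collapsed <- TRUE
    state$agents <- list()
    state$env <- env
    state$t <- state$t + 1L
    attr(state, "diagnostics") <- list(outcomes = outcomes,
                                       danger_deaths = danger_deaths,
                                       baseline_deaths = 0L, births = 0L)
    return(state)
  }

  # (vi) weights from post-danger, pre-baseline fitness
  weights <- reproduction_probabilities(
    vapply(survivors, `[[`, numeric(1), "cumulative_reward"))

  # (vii) baseline mortality; weights deliberately not recomputed
  baseline <- runif(length(survivors)) < config$baseline_death_prob
  baseline_deaths <- sum(baseline)
  survivors <- survivors[!baseline]
  weights <- weights[!baseline]
  if (length(survivors) == 0L) {
    state$collapsed <- TRUE
    state$agents <- list()
    state$env <- env
    state$t <- state$t + 1L
    attr(state, "diagnostics") <- list(outcomes = outcomes,
                                       danger_deaths = danger_deaths,
                                       baseline_deaths = baseline_deaths,
                                       births = 0L)
    return(state)
  }

  # (viii) replenish to n_agents
  births <- config$n_agents - length(survivors)
  survivor_index <- which(!fatal)[!baseline]
  state$agents <- replenish(survivors, weights, config)
  state$env <- env
  state$t <- state$t + 1L
  attr(state, "diagnostics") <- list(outcomes = outcomes,
                                     danger_deaths = danger_deaths,
                                     baseline_deaths = baseline_deaths,
                                     births = births,
                                     survivor_index = survivor_index)
  state
}

record_columns <- function() {
  c("t", "n_asocial", "n_observational", "n_parental", "n_advanced",
    "mean_f", "danger_deaths", "baseline_deaths", "n_births",
    "p_max", "p_min")
}

#' Run a full simulation
#'
#' Seeds the RNG from `config$seed`, initializes the environment and the
#' founder population, and iterates the per-step schedule (see
#' [time_step()]) `n_steps` times — or until collapse, i.e. every agent
#' dead within one step — recording one row of metrics per step. The step
#' loop runs in compiled code driven by R's RNG, so results are bit-for-bit
#' reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return An object of class `run_result`: a list with
#' \describe{
#'   \item{records}{data frame with columns `t`, per-strategy counts
#'     (`n_asocial`, `n_observational`, `n_parental`, `n_advanced`),
#'     `mean_f` (population mean cumulative reward), `danger_deaths`,
#'     `baseline_deaths`, `n_births`, `p_max`, `p_min` (population extrema
#'     of the preparedness loci).}
#'   \item{endpoint}{final population snapshot: `preparedness` and
#'     `q_values` matrices (agents x options), allele vectors, fitness,
#'     age, and a `strategy` factor.}
#'   \item{collapsed}{logical collapse flag.}
#'   \item{config}{the configuration echo.}
#' }
#' @export
#' @examples
#' cfg <- sim_config(n_agents = 30, n_steps = 200,
#'                   environment = env_config(danger_count = 2),
#'                   seed = 42)
#' run <- run_simulation(cfg)
#' tail(run$records[, 1:6])
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  e <- config$environment
  l <- config$learning
  m <- config$mutation
  lock <- !is.null(config$pure_strategy)
  pure_o <- if (lock)
    as.integer(config$pure_strategy %in% c("observational", "advanced"))
  else 0L
  pure_t <- if (lock)
    as.integer(config$pure_strategy %in% c("parental", "advanced"))
  else 0L
  res <- run_engine_cpp(config$n_agents, config$n_steps, e$n_options,
                        e$reward_min, e$reward_max, e$p_change,
                        e$danger_count, e$p_danger, e$p_newdanger,
                        l$alpha, l$fatal_reinforcement, l$q_init,
                        m$event_prob, m$epsilon_range,
                        m$preparedness_enabled,
                        config$baseline_death_prob,
                        pure_o, pure_t, lock, config$record_every)
  records <- as.data.frame(res$records)
  names(records) <- record_columns()
  alive <- as.logical(res$alive)
  endpoint <- list(
    preparedness = res$preparedness,
    q_values = res$q_values,
    obs_allele = as.integer(res$obs_allele),
    par_allele = as.integer(res$par_allele),
    cumulative_reward = as.numeric(res$f),
    age = as.integer(res$age),
    alive = alive,
    strategy = factor(strategy_from_alleles(res$obs_allele, res$par_allele),
                      levels = strategies()))
  structure(list(records = records, endpoint = endpoint,
                 collapsed = isTRUE(res$collapsed), config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<run_result> %d agents, %d steps%s, seed %s\n",
              cfg$n_agents, cfg$n_steps,
              if (x$collapsed) " (COLLAPSED)" else "",
              if (is.null(cfg$seed)) "none" else cfg$seed))
  cat(sprintf("  danger = %d, p_danger = %g, p_change = %g, p_newdanger = %g, preparedness %s\n",
              cfg$environment$danger_count, cfg$environment$p_danger,
              cfg$environment$p_change, cfg$environment$p_newdanger,
              if (cfg$mutation$preparedness_enabled) "on" else "off"))
  if (nrow(x$records) > 0L) {
    live <- x$endpoint$alive
    tab <- table(x$endpoint$strategy[live])
    cat("  endpoint strategies:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
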