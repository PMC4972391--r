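# small configuration builders shared across test files

tiny_sim <- function(..., n_agents = 20L, n_steps = 200L, seed = 1L) {
  sim_config(n_agents = n_agents, n_steps = n_steps, seed = seed, ...)
}

# a run_result built by hand, for metrics tests that need a known series
fake_run <- function(records, n_agents = 100L, window_start = 1L,
                     endpoint_strategy = "asocial", collapsed = FALSE,
                     preparedness_enabled = TRUE) {
  n_steps <- if (nrow(records)) max(records$t) else 0L
  cfg <- sim_config(n_agents = n_agents, n_steps = max(n_steps, 1L),
                    analysis_window_start = window_start,
                    mutation = mutation_config(
                      preparedness_enabled = preparedness_enabled),
                    seed = 1L)
  obs <- as.integer(endpoint_strategy %in% c("observational", "advanced"))
  par <- as.integer(endpoint_strategy %in% c("parental", "advanced"))
  endpoint <- list(
    preparedness = matrix(0, n_agents, 10),
    q_values = matrix(10, n_agents, 10),
    obs_allele = rep(obs, n_agents), par_allele = rep(par, n_agents),
    cumulative_reward = rep(0, n_agents), age = rep(0L, n_agents),
    alive = rep(TRUE, n_agents),
    strategy = factor(rep(endpoint_strategy, n_agents),
                      levels = strategies()))
  structure(list(records = records, endpoint = endpoint,
                 collapsed = collapsed, config = cfg),
            class = "run_result")
}

# records data frame with the fixed column set, given strategy counts
make_records <- function(t, n_asocial = 0, n_observational = 0,
                         n_parental = 0, n_advanced = 0, mean_f = 0,
                         danger_deaths = 0, baseline_deaths = 0,
                         n_births = 0, p_max = 0, p_min = 0) {
  data.frame(t = t, n_asocial = n_asocial,
             n_observational = n_observational, n_parental = n_parental,
             n_advanced = n_advanced, mean_f = mean_f,
             danger_deaths = danger_deaths,
             baseline_deaths = baseline_deaths, n_births = n_births,
             p_max = p_max, p_min = p_min)
}

modal_strategy <- function(run) {
  tab <- table(run$endpoint$strategy[run$endpoint$alive])
  names(which.max(tab))
}
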