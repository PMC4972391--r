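#' Bandit environment configuration
#'
#' The world is a multi-armed bandit: `n_options` discrete options, each
#' holding an integer reward drawn uniformly from
#' `[reward_min, reward_max]`. `danger_count` of the options are dangerous:
#' choosing one is fatal with probability `p_danger`. The environment is
#' temporally stochastic in two ways: with probability `p_change` per
#' time-step one option's reward is redrawn, and with probability
#' `p_newdanger` per time-step the identity of the dangerous options is
#' reassigned (evolutionarily novel dangers).
#'
#' @param n_options number of options (arms).
#' @param reward_min,reward_max inclusive integer reward range (reward units).
#' @param p_change per-step probability that one randomly selected option's
#'   reward is redrawn.
#' @param danger_count number of dangerous options, `0 <= danger_count < n_options`.
#' @param p_danger probability that choosing a dangerous option is fatal.
#' @param p_newdanger per-step probability that the dangerous set is
#'   reassigned; 0 keeps the same options dangerous for the whole run.
#' @return An object of class `env_config`.
#' @export
#' @examples
#' env_config(danger_count = 4, p_change = 0.05)
env_config <- function(n_options = 10L, reward_min = 0L, reward_max = 20L,
                       p_change = 0, danger_count = 0L, p_danger = 0.5,
                       p_newdanger = 0) {
  n_options <- as.integer(n_options)
  reward_min <- as.integer(reward_min)
  reward_max <- as.integer(reward_max)
  danger_count <- as.integer(danger_count)
  for (p in list(p_change = p_change, p_danger = p_danger,
                 p_newdanger = p_newdanger)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("probabilities must be single values in [0, 1]", call. = FALSE)
  }
  if (n_options < 1L)
    stop("'n_options' must be positive", call. = FALSE)
  if (reward_min > reward_max)
    stop("'reward_min' must not exceed 'reward_max'", call. = FALSE)
  if (danger_count < 0L || danger_count >= n_options)
    stop("'danger_count' must satisfy 0 <= danger_count < n_options",
         call. = FALSE)
  structure(list(n_options = n_options, reward_min = reward_min,
                 reward_max = reward_max, p_change = p_change,
                 danger_count = danger_count, p_danger = p_danger,
                 p_newdanger = p_newdanger),
            class = "env_config")
}

#' Initialize a bandit environment
#'
#' Draws each option's reward independently and uniformly over the integers
#' of `[reward_min, reward_max]`, and selects `danger_count` distinct
#' options uniformly at random (independently of their rewards) as the
#' dangerous set.
#'
#' @param config an [env_config()].
#' @return An object of class `env_state`: a list with integer vector
#'   `rewards` (length `n_options`) and sorted integer vector `dangerous`
#'   (1-based option indices).
#' @export
init_environment <- function(config) {
  stopifnot(inherits(config, "env_config"))
  rewards <- sample(config$reward_min:config$reward_max, config$n_options,
                    replace = TRUE)
  dangerous <- sort(sample.int(config$n_options, config$danger_count))
  structure(list(rewards = as.integer(rewards),
                 dangerous = as.integer(dangerous)),
            class = "env_state")
}

#' Advance the reward structure by one time-step
#'
#' With probability `p_change` exactly one uniformly chosen option has its
#' reward redrawn uniformly from the integer reward range; otherwise the
#' state is returned unchanged. At most one reward changes per call.
#'
#' @param state an [init_environment()] state.
#' @param config the matching [env_config()].
#' @return The (possibly updated) `env_state`.
#' @export
step_rewards <- function(state, config) {
  if (runif(1) < config$p_change) {
    o <- sample.int(config$n_options, 1L)
    state$rewards[o] <- sample(config$reward_min:config$reward_max, 1L)
  }
  state
}

#' Reassign the dangerous options
#'
#' With probability `p_newdanger` the dangerous set is reassigned: each
#' currently dangerous option in turn becomes safe and is replaced by an
#' option drawn uniformly from the options that are currently safe (never
#' itself), so previously dangerous options become safe and previously safe
#' options become dangerous. The set size is invariant and rewards are
#' untouched. With `danger_count = 1` this draws the new dangerous option
#' uniformly from the other `n_options - 1` options.
#'
#' @inheritParams step_rewards
#' @return The (possibly updated) `env_state`.
#' @export
step_danger <- function(state, config) {
  if (config$p_newdanger <= 0 || length(state$dangerous) == 0L)
    return(state)
  if (runif(1) < config$p_newdanger) {
    for (d in state$dangerous) {
      kept <- setdiff(state$dangerous, d)
      candidates <- setdiff(seq_len(config$n_options), c(kept, d))
      new <- candidates[sample.int(length(candidates), 1L)]
      state$dangerous <- sort(c(kept, new))
    }
  }
  state
}

#' Resolve the outcome of choosing an option
#'
#' Safe options always yield their current reward. Dangerous options yield a
#' fatal outcome with probability `p_danger`; the `reward` field still
#' carries the option's current reward, but a fatal outcome means the caller
#' must treat the agent as dead (the reward is never credited to a dying
#' agent's fitness — it only matters for observers' vicarious learning).
#'
#' @inheritParams step_rewards
#' @param option 1-based option index.
#' @return A list with fields `option`, `reward` and logical `fatal`.
#' @export
resolve_outcome <- function(state, option, config) {
  if (!is.numeric(option) || length(option) != 1L || is.na(option) ||
      option < 1 || option > config$n_options)
    stop("'option' out of range", call. = FALSE)
  option <- as.integer(option)
  fatal <- (option %in% state$dangerous) && (runif(1) < config$p_danger)
  list(option = option, reward = state$rewards[option], fatal = fatal)
}
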