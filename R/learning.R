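#' Learning parameters
#'
#' `alpha` is the Rescorla-Wagner learning rate, shared by individual and
#' observational updates. `fatal_reinforcement` is the vicarious
#' reinforcement an observer uses when the observed agent died (a large
#' negative value, -1000 by default: roughly fifty times the maximum
#' reward). `q_init` is the expected value every option starts at for
#' founders and for offspring without parental transmission; it equals the
#' average reward of the environment (10 for rewards uniform on 0..20).
#'
#' @param alpha learning rate, in (0, 1).
#' @param fatal_reinforcement reinforcement observed for fatal outcomes
#'   (reward units).
#' @param q_init initial expected value per option (reward units).
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(alpha = 0.3, fatal_reinforcement = -1000,
                            q_init = 10) {
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  structure(list(alpha = alpha, fatal_reinforcement = fatal_reinforcement,
                 q_init = q_init),
            class = "learning_params")
}

#' Softmax choice probabilities with a genetic prior
#'
#' The probability of choosing option i is proportional to
#' `exp(Q_i + P_i)`: the learned expected value plus the innate
#' preparedness bias compete for behavioural control at the decision
#' stage. The maximum effective value is subtracted before exponentiation
#' (mathematically identical, since softmax is invariant to adding a
#' constant) so arbitrarily large `Q + P` cannot overflow.
#'
#' @param q_values numeric vector of learned expected values.
#' @param preparedness numeric vector of preparedness loci, same length.
#' @return Numeric probability vector summing to 1.
#' @export
choice_probabilities <- function(q_values, preparedness) {
  if (length(q_values) != length(preparedness))
    stop("'q_values' and 'preparedness' must have equal length",
         call. = FALSE)
  eff <- q_values + preparedness
  w <- exp(eff - max(eff))
  w / sum(w)
}

#' Sample one option from a choice distribution
#'
#' @param probabilities numeric probability vector (as produced by
#'   [choice_probabilities()]).
#' @return A single 1-based option index.
#' @export
sample_choice <- function(probabilities) {
  sample.int(length(probabilities), 1L, prob = probabilities)
}

#' Rescorla-Wagner update of one option's expected value
#'
#' Only the chosen option changes: `Q <- Q + alpha * (R - Q)`, where the
#' prediction error `delta = R - Q` is the difference between received
#' reinforcement and the pre-update expectation.
#'
#' @param q_values numeric vector of expected values.
#' @param option 1-based index of the updated option.
#' @param reinforcement received reinforcement R (reward units).
#' @param alpha learning rate.
#' @return A list with the updated `q_values` and a `trace` (list with
#'   `option`, `reinforcement`, and prediction error `delta`).
#' @export
rw_update <- function(q_values, option, reinforcement, alpha) {
  if (option < 1 || option > length(q_values))
    stop("'option' out of range", call. = FALSE)
  delta <- reinforcement - q_values[option]
  q_values[option] <- q_values[option] + alpha * delta
  list(q_values = q_values,
       trace = list(option = as.integer(option),
                    reinforcement = reinforcement, delta = delta))
}

#' Reinforcement experienced vicariously by an observer
#'
#' Observational learning uses the observed agent's realized reward, except
#' that observing a fatal outcome substitutes the large negative
#' `fatal_reinforcement` — the only route by which danger can be learned
#' without dying.
#'
#' @param outcome an outcome list from [resolve_outcome()].
#' @param params a [learning_params()].
#' @return Reinforcement value (reward units).
#' @export
vicarious_reinforcement <- function(outcome, params) {
  if (isTRUE(outcome$fatal)) params$fatal_reinforcement else outcome$reward
}

#' Initial expected values for a founder or newborn
#'
#' Founders, and offspring without the parental-learning allele, start
#' every option at `q_init`. Offspring carrying `T1` (parental learning)
#' instead receive an exact, error-free copy of the parent's expected
#' values as they stand at the moment of reproduction.
#'
#' @param parent the parent agent (a list with element `q_values`), or
#'   `NULL` for founders.
#' @param genotype the offspring's [genotype()] (post-mutation).
#' @param params a [learning_params()].
#' @param n_options number of options.
#' @return Numeric vector of length `n_options`.
#' @export
initial_q_values <- function(parent, genotype, params, n_options = 10L) {
  if (genotype$par_allele == 1L && !is.null(parent))
    return(parent$q_values)
  rep(params$q_init, n_options)
}
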