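#' The four learning-strategy labels
#'
#' Fixed label order used throughout the package: `asocial` (O0 T0),
#' `observational` (O1 T0), `parental` (O0 T1), `advanced` (O1 T1).
#'
#' @return Character vector of length 4.
#' @export
strategies <- function() {
  c("asocial", "observational", "parental", "advanced")
}

#' Construct a genotype
#'
#' Heritable material of one agent: ten real-valued preparedness loci (one
#' per option, in reward units, added to learned values at the decision
#' stage) and two binary social-learning loci — `obs_allele` switches on
#' observational (horizontal) learning, `par_allele` switches on parental
#' (vertical) transmission of learned values.
#'
#' @param preparedness numeric vector of preparedness loci.
#' @param obs_allele,par_allele 0 or 1.
#' @return An object of class `genotype`.
#' @export
genotype <- function(preparedness = numeric(10), obs_allele = 0L,
                     par_allele = 0L) {
  obs_allele <- as.integer(obs_allele)
  par_allele <- as.integer(par_allele)
  if (!obs_allele %in% c(0L, 1L) || !par_allele %in% c(0L, 1L))
    stop("alleles must be 0 or 1", call. = FALSE)
  structure(list(preparedness = as.numeric(preparedness),
                 obs_allele = obs_allele, par_allele = par_allele),
            class = "genotype")
}

#' Founder genotype
#'
#' Populations start from asocial learners with no innate biases: all
#' preparedness loci at 0 and both social-learning alleles at 0.
#'
#' @param n_options number of preparedness loci (one per option).
#' @return A `genotype`.
#' @export
make_founder <- function(n_options = 10L) {
  genotype(preparedness = numeric(n_options), obs_allele = 0L,
           par_allele = 0L)
}

#' Classify a genotype's learning strategy
#'
#' Deterministic bijection between the (obs, par) allele pair and the four
#' strategy labels: (0,0) asocial, (1,0) observational, (0,1) parental,
#' (1,1) advanced.
#'
#' @param genotype a [genotype()].
#' @return One of [strategies()].
#' @export
classify_strategy <- function(genotype) {
  strategy_from_alleles(genotype$obs_allele, genotype$par_allele)
}

# vectorized allele -> label mapping used by metrics
strategy_from_alleles <- function(obs_allele, par_allele) {
  strategies()[1L + obs_allele + 2L * par_allele]
}

#' Mutation configuration
#'
#' At reproduction a single mutation event occurs with probability
#' `event_prob`; the mutated locus is chosen uniformly among the `n_loci`
#' heritable loci (10 preparedness + 2 learning loci by default), giving a
#' per-locus rate of `event_prob / n_loci` (0.0025 at the defaults). A
#' mutated preparedness locus receives an increment drawn uniformly from
#' `(-epsilon_range, +epsilon_range)`; a mutated learning locus flips its
#' allele. With `preparedness_enabled = FALSE` mutation events landing on
#' preparedness loci are silent (the locus stays 0), leaving the learning
#' loci's per-locus rate unchanged — this is the "without preparedness"
#' condition.
#'
#' @param event_prob per-offspring probability of one mutation event.
#' @param n_loci number of heritable loci.
#' @param epsilon_range half-width of the uniform preparedness increment
#'   (reward units).
#' @param preparedness_enabled logical; are preparedness mutations expressed?
#' @return An object of class `mutation_config`.
#' @export
mutation_config <- function(event_prob = 0.03, n_loci = 12L,
                            epsilon_range = 20, preparedness_enabled = TRUE) {
  if (event_prob < 0 || event_prob > 1)
    stop("'event_prob' must be in [0, 1]", call. = FALSE)
  if (epsilon_range <= 0)
    stop("'epsilon_range' must be positive", call. = FALSE)
  structure(list(event_prob = event_prob, n_loci = as.integer(n_loci),
                 epsilon_range = epsilon_range,
                 preparedness_enabled = isTRUE(preparedness_enabled)),
            class = "mutation_config")
}

#' Mutate a genotype at reproduction
#'
#' With probability `event_prob` one locus is chosen uniformly among the
#' `n_loci` heritable loci and mutated as described in
#' [mutation_config()]; otherwise the genotype is returned unchanged. At
#' most one locus changes per call. `lock_strategy = TRUE` (pure-strategy
#' populations) silences mutations landing on the learning loci while
#' leaving preparedness mutation untouched.
#'
#' @param genotype a [genotype()].
#' @param config a [mutation_config()].
#' @param lock_strategy logical; silence learning-locus flips?
#' @return The (possibly mutated) `genotype`.
#' @export
mutate <- function(genotype, config, lock_strategy = FALSE) {
  if (runif(1) >= config$event_prob)
    return(genotype)
  locus <- sample.int(config$n_loci, 1L)
  n_prep <- length(genotype$preparedness)
  if (locus <= n_prep) {
    if (config$preparedness_enabled)
      genotype$preparedness[locus] <- genotype$preparedness[locus] +
        runif(1, -config$epsilon_range, config$epsilon_range)
  } else if (locus == n_prep + 1L) {
    if (!lock_strategy) genotype$obs_allele <- 1L - genotype$obs_allele
  } else {
    if (!lock_strategy) genotype$par_allele <- 1L - genotype$par_allele
  }
  genotype
}
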