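---
title: "Methods: co-evolution of preparedness and social learning on a dangerous bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-evolution of preparedness and social learning on a dangerous bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`preplearn` simulates the joint evolution of two danger-coping
adaptations in a population of reinforcement-learning foragers: heritable
quantitative biases added to learned option values at the decision stage
(genetic preparedness), and heritable social-learning abilities
(horizontal observational conditioning and vertical transmission of
learned values). This vignette documents the model, its parameters, the
design decisions taken where the design was genuinely open, the
numerical choices, and the limits of what the simulations show.

## The model

**Environment.** A 10-armed bandit. Each option holds an integer reward
drawn uniformly from {0, …, 20} ("positive integer from [0, 20]" is read
as the inclusive integer range; its mean, 10, matches the initial
expected value given to agents). With probability `p_change` per step,
exactly one uniformly chosen option's reward is redrawn — a literal
reading of "one randomly selected option", so at most one reward moves
per step. `danger_count` options are dangerous; choosing one is fatal
with probability `p_danger` (default 0.5). Which options are dangerous is
unstated by the underlying design, so they are sampled uniformly without
replacement at initialization, independently of rewards — any coupling
to reward would bias the danger–reward association the agents are
supposed to discover. In novel-danger runs the dangerous set is
reassigned with probability `p_newdanger` per step: each dangerous
option in turn becomes safe and is replaced by a uniform draw from the
currently safe options (never itself). With one dangerous option this is
exactly "the previously dangerous option becomes safe and a previously
safe one becomes dangerous"; the sequential rule generalizes that to
larger sets while preserving set size and distinctness.

**Learning.** Expected values follow the Rescorla–Wagner rule with
learning rate `alpha` (0.3); only the chosen option's value moves.
Choice is softmax over `Q + P`, the learned value plus the preparedness
locus for that option. There is no temperature parameter; the exponents
are used as-is. Observational learners (`O1`) update once per step from
one uniformly chosen *other* agent's choice and outcome, with the same
`alpha`; a witnessed fatality is experienced as reinforcement
`fatal_reinforcement` (−1000, roughly fifty times the maximum reward —
large enough that one observed death makes an option effectively
unchoosable, which is the mechanism's point). Parental learners' (`T1`)
offspring receive an exact copy of the parent's `Q` vector as it stands
at the moment of reproduction, i.e. after the parent's own update that
step. Everyone else starts at `q_init` (10) per option. Social learning
carries no intrinsic cost or error anywhere — deliberately a best case.

**Selection.** Fitness is the cumulative reward accrued since birth. At
each step, after danger mortality and the agents' own updates,
reproduction weights are `f_i / max_j f_j`; each survivor then dies with
`baseline_death_prob` (0.02, giving a ~50-step expected adult lifespan);
finally the survivors, shuffled once into a random order and visited
cyclically, each produce one offspring per visit with probability equal
to their weight, until the population is back at `n_agents`. A single
shuffle followed by cyclic passes realizes "reproduced in a random
order" without re-shuffling bias. Offspring genotypes pass through the
mutation operator: one event per offspring with probability 0.03, locus
uniform among the twelve heritable loci (so 0.0025 per locus),
preparedness increments ε ~ U(−20, 20) treated as continuous (a
"uniformly distributed random number"), learning loci flipping
bidirectionally. Preparedness loci are unbounded in both directions — no
clamp is applied, and evolved values beyond the reward range are real
behaviour, not error. In "without preparedness" runs, mutation events
landing on preparedness loci are silent rather than redirected, which
keeps the learning loci's per-locus rate at exactly 0.0025 in both
conditions. In pure-strategy runs the learning loci are locked the same
way. Newborns never act, observe, or die within their birth step.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `n_agents` | 100 | agents | fixed population size |
| `n_steps` | 50000 | steps | analyses on `t >= analysis_window_start` (25000) |
| `n_options` | 10 | options | bandit arms |
| `reward_min..reward_max` | 0..20 | reward units | integer uniform |
| `p_change` | 0 / 0.005 / 0.05 | per step | stationary / between-generation / within-generation change |
| `danger_count` | 0–7 | options | the main experimental factor |
| `p_danger` | 0.5 | per choice | fatality risk of a dangerous choice |
| `p_newdanger` | 0 (0.001) | per step | danger relocation; 0.001 in novel-danger runs |
| `alpha` | 0.3 | — | learning rate, shared by individual and observational updates |
| `fatal_reinforcement` | −1000 | reward units | vicarious value of a witnessed death |
| `q_init` | 10 | reward units | environment's mean reward |
| `event_prob` | 0.03 | per offspring | single mutation event |
| `epsilon_range` | 20 | reward units | preparedness increment half-width |
| `baseline_death_prob` | 0.02 | per agent-step | danger-independent mortality |

## Numerical and degenerate-case choices

- **Softmax stabilization.** `exp(Q + P)` overflows once exponents pass
  ~709; mutation can push `P` far beyond that. The maximum effective
  value is subtracted before exponentiation — mathematically identical
  (softmax is shift-invariant) and stable up to arbitrarily large
  values. At extreme value gaps the distribution degenerates cleanly
  onto the maximum; strict monotonicity of probabilities in `Q + P`
  holds whenever the gaps keep all probabilities representable in double
  precision.
- **All-zero fitness.** At the very first steps every agent can have
  `f = 0`, making the weight denominator 0. Weights are then set equal,
  so early reproduction is unbiased rather than impossible.
- **Weights after baseline deaths.** Weights are computed before
  baseline mortality and deliberately not recomputed afterwards (the
  printed event order); dead agents are simply excluded as parents. If
  the maximum-fitness agent dies there and every remaining survivor has
  `f = 0`, all remaining weights are 0 and replenishment would never
  terminate; the weights then fall back to all-equal, mirroring the
  all-zero-fitness rule.
- **Fatal choices.** A dying agent's own `Q` and fitness are never
  updated; its outcome is visible to observers (observation precedes
  removal in the event order). An agent that survives a dangerous choice
  updates with the option's ordinary reward — dangerous options can be
  associated with reward. The reward field of a fatal outcome is carried
  for observers but never credited to the dying agent.
- **Collapse.** If every agent dies within one step (possible at high
  danger with relocating dangerous options) the run terminates
  gracefully with a `collapsed` flag and truncated records, rather than
  erroring.
- **Observation targets.** Each observer draws its target uniformly and
  independently from the other agents that acted this step; two
  observers may watch the same target, and agents about to die are valid
  targets.

The step loop of `run_simulation()` is compiled (Rcpp) but consumes R's
RNG, so runs are bit-reproducible from `set.seed`; the exported R
operations (`time_step()`, `replenish()`, `mutate()`, …) implement the
identical semantics operation-by-operation and are the reference the
test suite exercises directly. The two paths draw random numbers in
different orders, so they are statistically — not stream-wise —
equivalent.

## Experiment designs

`sweep_spec()` crosses danger levels (0–7), change rates ({0, 0.005,
0.05} by default; the set is configurable since the full grid used for
the original figures is not enumerable from the text), preparedness
conditions, and replicates (100 for the mixed design, 10 for
pure-strategy and novel-danger designs). Replicate seeds derive
deterministically from `base_seed` and the cell index, collision-free
across the grid. `run_experiment()` streams every run to CSV/JSON and is
resumable; aggregates are always rebuilt from the on-disk files so a
resumed experiment is byte-identical to an uninterrupted one.

The test suite validates the headline behaviours at these problem
sizes, chosen to estimate each direction with comfortable margins: 20
replicates of full 50000-step runs for strategy dominance in dangerous
stochastic environments, 10 matched pairs for the
foraging-efficiency/death-risk trade-off at `danger = 4`,
`p_change = 0.05` (a stochastic environment, where the foraging cost of
preparedness is expressed), 10 replicates per danger level at
`p_change = 0.005` for the preparedness extrema, and 10 replicates per
preparedness condition at `p_change = 0.05` for the novel-danger design.
Where the original analyses averaged across change rates, these single
intermediate or rapid rates were fixed once as representative
conditions.

## What the simulations do and do not show

The generator *is* the study system: there is no external data, and
every test statement is about this model, not about any natural
population. The model omits spatial structure, option depletion,
frequency-dependent payoffs, diploidy and recombination, gradual
parent–offspring co-residence, and any intrinsic cost of social
learning. Conclusions about real foragers therefore rest entirely on the
model's empirical grounding (Rescorla–Wagner learning, softmax choice,
vicarious reinforcement), not on these simulations.

Two behaviours deserve explicit note:

- Because social learning is cost-free and error-free, it confers a
  real advantage even in perfectly safe, stationary environments:
  observational learners converge on good options faster, and vertical
  transmission spares offspring the newborn exploration phase. In our
  runs the asocial founders are therefore reliably displaced by
  social-learning phenotypes within ~20000 steps even at
  `danger_count = 0`, `p_change = 0` — and with bidirectional mutation
  at 0.0025 per locus per birth, the founder state would wash out by
  drift over 50000 steps even under strict neutrality. Safe stationary
  environments distinguish the *strategies'* relative success far less
  than dangerous ones do; expecting asocial persistence there would
  require an intrinsic cost of social learning that this model
  deliberately does not impose.
- Evolved preparedness values routinely leave the reward range (positive
  maxima above +20, minima far below 0). This is genuine: nothing bounds
  the loci, and the decision rule only cares about differences
  `Q_i + P_i − (Q_j + P_j)`.
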