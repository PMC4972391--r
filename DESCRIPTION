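Package: preplearn
Title: Evolutionary Simulation of Genetic Preparedness and Social Learning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based evolutionary simulation of reinforcement-learning
    foragers on a dangerous multi-armed bandit. Haploid agents carry ten
    heritable quantitative loci (genetic preparedness) that are added to
    learned option values at the decision stage, plus two binary loci that
    switch on observational (horizontal) and parental (vertical) social
    learning. Individual and observational learning follow the
    Rescorla-Wagner rule with softmax choice; reproduction is
    fitness-proportional with rare single-locus mutation. The package
    provides the per-step scheduler, per-run and cross-run summary metrics,
    replicated experiment sweeps with deterministic seeding, and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
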