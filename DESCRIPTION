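Package: mkdipobc
Title: Knowledge-Driven Dirichlet Priors for Optimal Bayesian
    Classification of Boolean Network Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction of maximal knowledge-driven information priors
    (MKDIP) for discrete optimal Bayesian classification.  Boolean gene
    regulatory networks with perturbation are turned into exact Markov-chain
    steady-state distributions that define two-class multinomial
    classification problems; regulating functions are compiled into
    conditional-probability constraints on Dirichlet hyperparameters; the
    prior is obtained by minimising an information-theoretic cost (maximum
    entropy, maximal data information, or expected mean log-likelihood)
    subject to those constraints with penalised slackness variables.
    Includes the discrete optimal Bayesian classifier, exact error
    evaluation, Gibbs-sampled inference for unlabeled multinomial mixtures,
    and a Monte-Carlo experiment harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
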