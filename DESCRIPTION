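Package: karyorate
Title: Trait-Dependent Rates of Chromosome-Number Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time Markov models of haploid chromosome-number
    evolution (fusions, fissions, whole-genome duplication) whose rates may
    depend on a binary life-history trait such as winglessness. Provides
    Felsenstein pruning likelihoods with probabilistic tip states, Bayesian
    slice-sampling MCMC replicated over posterior tree sets with tip-count
    resampling, posterior rate-difference (Delta-R) and clade mean-rate
    summaries, fossil-scaled coefficient-of-variation comparators, and a
    synthetic-data generator (Yule trees, perturbed tree sets, exact
    stochastic character simulation, genus-level trait imputation) so the
    whole workflow is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
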