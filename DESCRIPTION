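Package: cnavhmm
Title: Bayesian Hidden Markov Models for Copy-Number and Allelic Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models population genotype distributions at loci with joint
    copy-number and allelic variation (CNAV) as the output of a stochastic
    finite-state machine: a user-defined directed hidden Markov model graph
    is walked twice per individual, and the summed emission counts form an
    MLPA-style integer genotype.  The graph encodes an extension of the
    Hardy-Weinberg equilibrium with gain and loss recursion loops.
    Transition probabilities are inferred with a data-augmented
    Metropolis-within-Gibbs sampler (conjugate MatrixDirichlet updates,
    rejection-based latent path-pair refreshes, and a symmetric bounded
    tree-search kernel as backup).  Model comparison uses Chib-Jeliazkov
    marginal likelihoods against a naive Dirichlet-multinomial enumeration
    model; further tools translate non-phased genotypes into haplotype-phased
    genotypes via alternative emission sets and dissect multimodal
    posteriors by restarts, k-means clustering and per-mode evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
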