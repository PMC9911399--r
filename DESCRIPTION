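Package: hitseq
Title: Simulation and Analysis of Equilibrium-Binding Sequencing (HiTS-Eq) Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for High Throughput Sequencing Equilibrium binding
    (HiTS-Eq) experiments, in which the unbound fraction of a randomized
    RNA pool is sequenced at a series of protein concentrations and
    per-variant relative binding affinities are inferred from depletion.
    Includes a simulator for randomized 7-mer RNA libraries with
    ground-truth dissociation constants, read demultiplexing and
    UMI-aware counting, relative-affinity estimation from a competitive
    binding scheme, quadratic and competition binding-isotherm fits,
    projection of 7-mer affinities onto 5-mer space, position weight
    matrix (PWM) and pairwise-coupling (PWC) regression models of
    log-affinity, and affinity-distribution analytics (bimodality
    assessment, sequence logos, specificity ratios, RBNS R-score
    normalization).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
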