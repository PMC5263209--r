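Package: mpqtl
Title: Multiparent QTL Mapping with Founder-Probability Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multiparent recombinant-inbred-line
    (RIL) populations of the backcross-intercross type used in barley
    pre-breeding. Provides a breeding-design simulator (donor x recipient
    crosses, one backcross, pairwise intercross, single seed descent),
    founder-origin probability inference by a hidden Markov model, a
    three-stage REML mixed-model genome scan with random founder effects and
    cross-specific residual variances, heterogeneous-inbred-family fine
    mapping, near-isogenic-line transcript variant filtering and
    introgression mapping, and phenotype summaries (broad-sense heritability,
    relative trait ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
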