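Package: omnimeta
Title: Multi-Study Transcriptomics Meta-Analysis with Quality Control and
    Signature-Reversal Compound Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for meta-analysis of multiple normalized gene
    expression studies: inter-array-correlation sample quality control,
    six-measure study-level quality scoring with standardized-mean-rank
    exclusion, per-study differential expression by penalized t statistics
    with label-permutation p-values and Hedges g effect sizes, combination
    across studies by p-value methods (Fisher, Stouffer, maxP, rOP with
    one-sided direction correction), rank methods (product and sum of
    ranks) and fixed/random effects pooling (DerSimonian-Laird),
    consensus signature calling, hypergeometric over-representation
    analysis, and prioritization of compounds whose perturbation
    signatures reverse the disease signature. Includes a synthetic
    multi-study generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
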