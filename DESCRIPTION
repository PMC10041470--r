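Package: neurodevnet
Title: Multilayer Network Maturation, Imaging Transcriptomics and Risk Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytic cascade linking early-life adversity and polygenic risk to
    task-fMRI multilayer network maturation, its transcriptomic and receptor
    correlates, and psychopathology. Implements Fisher-z task connectomes,
    multilayer generalized-Louvain modularity with flexibility and recruitment
    diagnostics, cross-validated canonical correlation and behavioural partial
    least squares with permutation nulls and bootstrap reliability, spatially
    constrained (spin) permutations on the sphere, robust-sigmoid gene
    expression normalisation with a stress-gene overlap test, polygenic risk
    scoring with standard SNP filters, and moderated mediation with percentile
    bootstrap. A synthetic-data generator with planted effects provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    sandwich
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
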