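Package: fieldcanceR
Title: Whole-Organ Analysis of Mucosal Field Cancerization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-organ maps of epithelial field cancerization:
    spatial classification of mutations into private low-frequency (alpha),
    regional (beta) and widespread clonal (gamma) classes from per-field
    variant allele frequencies; VAF-distribution clonality diagnostics;
    96-context mutational-signature refitting with bootstrap significance;
    maximum-parsimony phylogeny of mucosal fields with branch clustering;
    a clock-calibrated branching-process surrogate that assigns mutation
    ages and selection coefficients and partitions carcinogenesis into
    dormant and progressive phases; and monotonic dysregulation calling
    with stage scores, single-sample enrichment and Fisher pathway
    enrichment across RNA, protein and metabolite layers. Includes a
    synthetic whole-organ generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
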