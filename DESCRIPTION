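Package: clonetrace
Title: B Cell Receptor Repertoire Networks, Clonal Sharing and
    Immunosurveillance Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing B cell receptor (BCR) and T cell receptor
    repertoires across multiple tumour sites and therapy timepoints:
    clonotype assembly via single-nucleotide sequence networks and
    CDR3-identity clustering, depth-matched subsampled clonal-sharing
    statistics (shared VDJ counts and Jaccard coefficients), Ward-D2
    similarity dendrograms with cophenetic concordance and permutation
    tests against tumour phylogenies, stem/clade/private topology and
    expansion-based clone classes, repertoire diversity (Gini, Shannon,
    mean clone size) under UMI subsampling, somatic-hypermutation and
    isotype profiling, per-clone minimum-spanning-tree lineage graphs
    with degree-centrality prediction of immunosurveilling and
    temporally persistent BCRs, fuzzy CDR3 screening against reference
    anti-pathogen antibody libraries, and a synthetic repertoire
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    caret,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
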