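Package: sublocr
Title: Multi-Label Prediction of Eukaryotic Protein Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular location sites of eukaryotic proteins,
    including multiplex proteins that reside in two or more compartments.
    Proteins are encoded in three complementary pseudo amino acid composition
    modes: a Gene Ontology indicator vector transferred from BLAST homologs, a
    conserved functional-domain indicator vector, and a pseudo position-specific
    scoring matrix (Pse-PSSM) descriptor combining per-residue evolutionary mean
    scores with lag correlation factors. Classification uses ensembles of
    evidence-theoretic K-nearest-neighbor voters fused by Dempster's rule, with
    a threshold-based multi-label decision. Includes a leave-one-protein-out
    jackknife evaluator with virtual-sample accounting and penalized success
    rates, a fully synthetic benchmark generator so the whole pipeline is
    testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
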