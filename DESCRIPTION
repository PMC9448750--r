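Package: ffpecorrect
Title: Correction of Formalin-Fixation Artefacts in Mutational Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mutational signature analysis of formalin-fixed
    paraffin-embedded (FFPE) tumour samples. Formalin deaminates cytosine
    (and 5-methylcytosine) and floods sequencing data with artefactual C>T
    calls. The package models an observed 96-channel single-base-substitution
    catalogue as a linear combination of a fixed FFPE artefact signature and a
    free biological spectrum, fitted by multiplicative-update minimisation of
    the generalized Kullback-Leibler divergence with restart averaging. It
    also derives artefact signatures from labelled cohorts of FFPE profiles
    (stochastic embedding plus density-based representative selection),
    refits activities of fixed signature sets with presence calls and error
    metrics, supports the 80-channel (non-T>C) spectrum, and ships a
    synthetic-cohort simulator with Poisson artefact injection for
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    VariantAnnotation,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    SummarizedExperiment
Config/testthat/edition: 3
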