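Package: logomhc
Title: Logo-Model Prediction of Peptide Binding to HLA-DRB1*03:01
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Position-specific quantitative matrices (QMs) for MHC class II
    peptide-binding prediction, built from amino-acid frequencies in the
    nonamer binding core by mean normalization. Fits a two-matrix "logo
    model" (one QM for binders, one for non-binders to HLA-DRB1*03:01),
    scores nonamers (binding score BS, non-binding score NBS), classifies
    peptides of any length through overlapping nonamer windows, evaluates
    classifiers with six summary statistics including Matthews' correlation
    coefficient, and scans protein sequences for strong binders (BS > 2)
    as immunotherapy candidates. Ships the published binder and non-binder
    matrices as plain-text fixtures plus seeded synthetic peptide-set
    generators so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
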