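Package: kermed
Title: Kernel-Based High-Dimensional Mediation Analysis for Multi-Omic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for high-dimensional mediation analysis (HDMA) of
    genome, transcriptome, and phenome data measured on the same
    individuals. Each modality is normalized and converted to a centered
    linear kernel; composite individual-level scores are then fit so that
    the genome-to-phenome path is carried entirely through the
    transcriptome score (the perfect-mediation constraint). Includes
    permutation tests for the mediated path coefficient, partitioning of
    per-transcript heritability into local and distal components by
    two-kernel restricted maximum likelihood, transfer of transcript
    loadings to independent populations from measured or locally-imputed
    expression, and a multiparent-population simulator with controllable
    local and distal heritability for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
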