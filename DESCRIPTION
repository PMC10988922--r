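Package: insituanno
Title: Validate Single-Cell Annotations Against In Situ Reference Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-round correlation pipeline for validating single-cell RNA-seq
    cell-type annotations against laser-capture-microdissection (LCM) bulk
    reference transcriptomes. Round one correlates every single cell with every
    bulk reference sample; round two correlates each candidate marker gene's
    expression across cells with those per-cell similarities, yielding
    replicate-level concordance scores, between-type t-tests with significance
    stars, marker type calls, and consistency flags against the claimed types.
    Includes an expressed-gene overlap comparison between datasets, readers and
    writers for 10x-style MatrixMarket triplets and dense TSV matrices, CPM and
    log-CPM normalization, and a negative-binomial synthetic-data generator
    with planted marker ground truth so the whole analysis is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
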