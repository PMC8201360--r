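Package: bioactpep
Title: Bioactive Peptide Prediction and Comparative Peptidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: High-throughput prediction of bioactive peptide properties from
    amino-acid sequences using a 407-element physicochemical descriptor
    (molecular mass, length, hydropathy, charge counts and the 400 ordered
    dipeptide frequencies) and paired k-nearest-neighbour / random-forest
    classifiers per property, combined by consensus voting.  Also provides a
    comparative peptidomics pipeline for peptide presence/abundance tables
    across species: presence calling by replicate maximum, mean centering,
    one-way ANOVA screening, core/variable peptide partition, hierarchical
    and k-modes pattern clustering, and correspondence analysis of
    pattern-by-species contingency tables.  Includes a synthetic-data
    generator with planted ground truth so every stage is testable, and a
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
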