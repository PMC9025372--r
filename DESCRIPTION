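Package: cellmark
Title: Marker-Gene Discovery for Multi-Class Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A feature-selection pipeline for identifying cell-type marker
    genes in labelled single-cell expression matrices. Genes are screened by
    mutual information with the cell-type label, confirmed against shadow
    (permuted) features with a random-forest importance test, ranked by Monte
    Carlo feature selection on random feature projections, and then swept by
    incremental feature selection with SMOTE-balanced stratified
    cross-validation scored by the multiclass Matthews correlation
    coefficient. The final decision tree is converted into ranked IF-THEN
    classification rules. Includes a synthetic-data generator with planted
    class-specific markers and class imbalance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    ranger,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
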