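Package: apocrine
Title: Transcriptomic and Genomic Profiling of Familial Breast Tumours
    with Apocrine Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline for cohort studies of familial
    breast cancer with a molecular apocrine component: microarray probe-set
    filtering (intensity, chi-square variance test, robust coefficient of
    variation), unsupervised Ward clustering on 1-Pearson dissimilarity,
    nearest-centroid intrinsic-subtype assignment, supervised signature
    derivation (Welch t-test, local false-discovery-rate screening, random
    forest importance selection), hypergeometric gene-set and
    signature-overlap testing, two-component PCA with model-based
    clustering, BAC-clone array-CGH gain/loss/amplicon calling with a
    per-arm genomic perturbation rate, and immunohistochemistry scoring
    with chi-square/Fisher contingency analysis. Includes a synthetic-data
    generator emulating the cohort structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
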