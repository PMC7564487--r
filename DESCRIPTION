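Package: thyrofish
Title: Copy-Number Marker Discovery and Triple DNA FISH Scoring for
    Thyroid Follicular Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to separate classic follicular thyroid adenoma (cFA)
    from classic follicular thyroid carcinoma (cFTC) using somatic
    copy-number markers. Implements an array-CGH analysis chain
    (GC/dye normalization, circular binary segmentation with seeded
    permutation testing, noise-adaptive gain/loss calling), greedy
    selection of minimal discriminating chromosomal regions, scoring of
    triple DNA FISH nucleus counts (1p36/1q25, 22q13/22q11, CEP X/Y),
    DNA-index ploidy classification, and pooled diagnostic accuracy
    statistics with exact binomial confidence intervals and
    prevalence-adjusted predictive values. A synthetic-cohort generator
    emulates the statistical structure of two-class aCGH and FISH
    studies so the whole pipeline can be exercised end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
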