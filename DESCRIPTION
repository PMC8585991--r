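Package: plsct
Title: Imaging Transcriptomics of Cortical Thickness Differences via
    Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links regional cortical-thickness differences between two
    clinical groups (for example stable versus converting mild cognitive
    impairment) to regional gene expression. Fits a single-response
    partial least squares regression of the per-region thickness
    difference on a region-by-gene expression matrix, selects the number
    of components by cross-validation, assesses the variance explained by
    each component against a permutation null, and standardizes gene
    weights by bootstrap resampling of regions with Benjamini-Hochberg
    false-discovery-rate control. Downstream tools profile component
    scores across cytoarchitectonic (Von Economo) cortical classes and
    test significant gene lists for overlap with cell-type marker sets by
    permutation and exact hypergeometric tests. Includes a synthetic-data
    generator with a planted linear expression-to-thickness signal so the
    whole pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    yaml,
    optparse
Config/testthat/edition: 3
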