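Package: refstab
Title: Reference Gene Validation and qPCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workflow for selecting and validating qPCR reference genes
    and quantifying relative expression. Screens candidate reference genes
    from RNA-Seq results tables (expression-level, fold-change, significance
    and dispersion filters with quartile-stratified sampling), aggregates
    technical-replicate Cq values under a replicate-consistency rule,
    performs coefficient-of-variation screening of linearized expression,
    ranks candidates with a model-based variance-components stability
    estimator (NormFinder) including an exhaustive best-pair search, builds
    per-sample normalization factors from the best pair, quantifies target
    genes by the 2^-ddCt method, and compares fold-change distributions
    across normalization strategies with Kruskal-Wallis and Dunn's
    control-versus-others post test. Includes seeded simulators for Cq
    datasets and negative-binomial count matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
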