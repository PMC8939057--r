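Package: raschshort
Title: Rasch-Based Shortening of Polytomous Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shortening polytomous rating scales with the partial
    credit Rasch model. Provides conditional maximum likelihood estimation of
    item thresholds, person measurement with extreme-score handling, the four
    classical item-fit indicators (fit residuals, item-trait chi-square,
    threshold ordering, residual correlations), Smith's principal-component
    test of unidimensionality, differential item functioning analysis by
    two-way ANOVA on standardized residuals with artificial-DIF resolution,
    testlet (subtest) analysis with latent correlations and explained common
    variance, an iterative one-item-per-subscale elimination pipeline that
    combines the statistical indicators with subject-matter content flags,
    and ordinal-to-interval conversion tables that map raw mean scores to a
    linear 1-5 metric through person logits. A synthetic-data module
    generates unidimensional and multidimensional (testlet-structured)
    partial-credit responses with optional injected differential item
    functioning and stratified subsampling, for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
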