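Package: svyconcord
Title: Concordance of Prevalence Estimates Between Field and Public Household Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying agreement between prevalence-type health
    indicator estimates reported by small field (NGO-style) baseline surveys
    and matched estimates from large public household surveys such as the
    Demographic and Health Surveys (DHS) and Multiple Indicator Cluster
    Surveys (MICS). Implements most-recent-prior survey cycle matching with
    administrative-hierarchy fallback, paired difference metrics, within-band
    concordance and stratified summaries, sequential (Type I)
    analysis-of-variance partitioning of difference variance, a binomial
    sampling-error Monte Carlo, and a synthetic two-source survey generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
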