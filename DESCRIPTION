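Package: dsdn
Title: Voxel-Wise Profiling of Non-Stationarity and Non-Linearity in
    Resting-State fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the degree of stationarity (DS) of voxel-wise
    BOLD time series via empirical mode decomposition and the Hilbert
    marginal spectrum, and the degree of non-linearity (DN) via delay
    vector variance analysis against iAAFT surrogate ensembles.
    Provides quartile-fence classification into weak/medium/strong
    levels, DS-by-DN overlap maps, seven-network atlas summaries,
    two-way ANOVA intraclass-correlation test-retest reliability, and
    network/slice similarity analyses, together with a synthetic
    multi-subject multi-session dataset generator with known
    stationarity and linearity classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
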