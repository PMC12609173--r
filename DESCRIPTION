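Package: cascnet
Title: Causal Structural Covariance Networks for Lesion-Driven Grey-Matter Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders cross-sectional grey-matter morphometry by white-matter
    hyperintensity (WMH) burden into a pseudo-time series and maps signed
    lag-1 Granger-causal influence from a seed region (causal structural
    covariance networks). Includes a synthetic-cohort generator with planted
    propagation and mediation ground truth, mass-univariate group contrasts
    with permutation cluster-level FDR, WMH severity staging, directed
    weighted network metrics and modularity, binomial forward-inference
    decoding, and bias-corrected bootstrap mediation of cognition by
    grey-matter volume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
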