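Package: chromaspec
Title: Spectral Deconvolution and Fingerprint Classification for
    Full-Spectrum Liquid Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An unsupervised chemometric pipeline for absorbance data recorded
    over both elution time and wavelength, as produced by liquid chromatography
    with a broadband UV-vis detector. Detects chromatographic peaks, estimates
    the number of co-eluting species in congested elution windows by principal
    components analysis and K-means clustering with the elbow criterion,
    resolves overlapping and fully hidden peaks by Gaussian elution-model
    fitting followed by multivariate curve resolution with alternating
    non-negative regression, and identifies each recovered spectrum against a
    reference library using a variance-projected linear discriminant
    fingerprint classifier with an r-squared tiebreak, independent of
    retention time. Includes a synthetic-data generator emulating Beer-Lambert
    linear mixing of Gaussian elution profiles, so every stage is testable
    without instrument data.
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
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
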