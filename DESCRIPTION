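Package: patchslope
Title: Variance-Slope Analysis of Plankton and Physical Patchiness Along
    Underway Ocean Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies spatial patchiness of physical and biological
    properties measured by shipboard flow-through (underway) systems using
    the variance slope: the exponent G of the power law V = L^G relating
    within-window variance V to window length L, estimated over
    log-distributed windows on 500-sample transect legs. Unlike Fourier
    spectral slopes, the estimator tolerates data gaps of up to 20% of a
    leg. Includes a synthetic-data module generating power-law transects,
    ship tracks, gappy multivariable underway streams, and raw 4 Hz
    hyperspectral absorption/attenuation streams with known ground truth;
    processing of raw optics into per-minute particulate spectra
    (percentile-trimmed minute binning, filtered-seawater baseline
    subtraction); optical proxies (chlorophyll line height at 676 nm,
    particle-size exponent gamma, particulate attenuation at 443 nm); leg
    segmentation and quality control; and the comparative layer
    (variance-slope cross-correlations, province aggregation,
    slope-versus-magnitude relations, spatial autocorrelograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
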