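Package: ffpshg
Title: Fast Fourier Analysis of Polarization-Resolved Second Harmonic
    Generation Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise recovery of collagen structural parameters from
    polarization-resolved second harmonic generation (PSHG) microscopy
    image stacks using the single-axis molecule model and a discrete
    Fourier transform inversion (FF-PSHG). Produces planar maps of the
    second-order susceptibility tensor ratios (chi31/chi15, chi33/chi15,
    chi33/chi31), the in-plane collagen orientation, and the helical
    pitch angle, together with per-pixel fitting-quality estimators
    (coefficient of determination, spectral error ratio,
    signal-to-noise ratio) and local dispersion maps (entropy, standard
    deviation, median absolute deviation) over square and circular
    windows. Includes a synthetic phantom-stack generator, readers and
    writers for the PSHG-TISS collection layout, and a
    collection-manifest validator.
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
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
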