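Package: viscomplex
Title: Objective Measurement of Perceived Visual Complexity in Streetscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the visual complexity of streetscape photographs from the
    statistics of local contrast and local spatial frequency. Dense RMS-contrast
    maps and independent-component (IC) filter-response kurtosis maps are
    computed over sliding image neighborhoods and summarised into a single
    objective measure M. Includes the FastICA learning stage for the
    high-frequency IC filter bank with Gabor characterisation of the learned
    filters, anti-aliased image decimation for display presentation, aggregation
    of per-subject grouped complexity rankings into a mean-rank order,
    correlation reports against objective measures, and four conventional
    clutter baselines (edge-perimeter length, JPEG file size, wavelet subband
    entropy, and Nasanen's area-times-median-frequency measure). A synthetic
    fixture generator provides edge and grating control stimuli, streetscape
    surrogate scenes with known construction complexity, ICA training textures,
    and simulated participant rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    png,
    tiff,
    jpeg,
    minpack.lm,
    jsonlite,
    digest,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
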