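Package: nanosip
Title: NanoSIMS Stable-Isotope-Probing Quantification of 15N Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies single-cell 15N stable-isotope-probing experiments
    from NanoSIMS dual ion-count images (12C14N- and 12C15N- secondary
    ions). Aggregates counts over regions of interest into isotope ratios
    and atom percent 15N with Poisson counting-error propagation, calls
    significant enrichment against unlabeled-control distributions with a
    dual criterion (above the 95th percentile of controls and 2-sigma
    smaller than the excess over the control mean), summarises enrichment
    per biological component, renders greyscale structure and hue-encoded
    ratio (HSI) images with line scans, and generates synthetic Poisson
    ion-count scenes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
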