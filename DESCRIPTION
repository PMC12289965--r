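Package: sdmscope
Title: Simulated Self-Driving Microscopy for Protein Aggregation and
    Brillouin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of an event-triggered
    ("self-driving") microscopy pipeline for studying protein aggregation
    in living cells. Provides a generative virtual microscope (multi-plane
    fluorescence time lapses, brightfield images, per-pixel Brillouin
    spectra with ground truth), a training and evaluation harness for
    aggregation-onset and aggregate-presence classifiers, a two-mode
    event-triggered acquisition engine running against a virtual clock,
    and a Brillouin quantification chain (Lorentzian spectral fitting,
    instrumental-linewidth deconvolution, Otsu segmentation, and
    region statistics), so the control logic and analysis chain can be
    tested end-to-end without microscope hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
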