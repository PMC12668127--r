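Package: hdnmr
Title: Simulation and Processing of Sensitivity-Enhanced High-Dimensional NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and processing pipeline for sensitivity-enhanced
    multidimensional (2D-5D) solid-state NMR experiments. Generates hypercomplex
    time-domain data under conventional cross-polarization (States/States-TPPI)
    or preserved-pathway (echo-antiecho, transverse-mixing optimal-control pulse)
    transfer schemes, performs Rance-Kay recombination and hypercomplex Fourier
    processing, supports non-uniform sampling with direct nuFT, point-spread
    functions and iterative-thresholding reconstruction, and implements
    plane-based SNR estimation together with the closed-form calculus of
    expected enhancement, break-even bulk signal and measurement-time
    equivalents for experiments with multiple enhanced indirect dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
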