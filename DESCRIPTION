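Package: seednir
Title: Seed Viability Classification from FT-NIR Spectra with PLS-DA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for screening naturally aged seeds as
    viable or nonviable from Fourier-transform near-infrared (FT-NIR)
    absorbance spectra. Provides a SummarizedExperiment-based container for
    labelled spectra, the standard spectral preprocessing menu (maximum,
    mean and range normalization, standard normal variate, multiplicative
    scatter correction, Savitzky-Golay derivatives, region trimming), a
    from-scratch NIPALS PLS-DA implementation with cross-validated latent
    variable selection and a +/-0.5 class-code decision rule, variable
    importance in projection (VIP) scoring with threshold-scan variable
    selection, Hotelling's T2 and Q-residual outlier diagnostics, ROC and
    confusion-matrix evaluation, and a synthetic FT-NIR seed-spectra
    generator for end-to-end validation of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Preprocessing, Spectroscopy, DimensionReduction
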