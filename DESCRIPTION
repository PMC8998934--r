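Package: t2flux
Title: T2 Relaxometry, Tumor Volumetry and Bioluminescence Calibration for
    Preclinical Brain-Tumor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantitative follow-up of orthotopic
    brain-tumor xenografts imaged by multi-slice multi-echo MRI and
    bioluminescence. Provides pixel-wise T2 relaxation mapping by
    nonlinear least-squares fitting of the mono-exponential decay,
    echo-averaged contrast images, threshold plus largest-connected-
    component tumor volumetry, Bland-Altman agreement analysis between
    contrast methods, bioluminescence total-flux processing (background
    subtraction, best-of-three selection, week-1 normalization), log-log
    power-law calibration of flux against tumor volume with residual
    analysis, and Kaplan-Meier survival summaries with log-rank and
    Mann-Whitney comparisons. A digital-phantom generator produces
    synthetic multi-echo stacks, flux tables and survival cohorts with
    known ground truth so the whole chain is testable without animal
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    survival,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
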