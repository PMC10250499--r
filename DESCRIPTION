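Package: semiq
Title: Semi-Targeted Quantification and Spectral Library Curation for
    LC-MS/MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A batch, scriptable engine for semi-targeted quantification of
    compounds with known mass-to-charge ratio and retention time from
    data-dependent acquisition (DDA) LC-MS/MS runs. Implements an
    eight-step quantification chain (extracted ion chromatogram (EIC)
    extraction, smoothing, noise estimation, peak selection, integration,
    screening, identification, and batch optimization), internal-standard
    based retention-time calibration, compound-by-compound multi-file peak
    alignment, retention-time pattern refinement, curation of inspected
    MS2 spectra into a reusable spectral library (MSP), and a synthetic
    DDA run generator with ground truth for validation, including a
    two-mixture benchmark with known concentration ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
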