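Package: pathsig
Title: Bayesian Inference of Signal Transduction Pathway Activity from
    Target Gene Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Knowledge-based assessment of signal transduction pathway
    activity from mRNA measurements of curated direct target genes. A
    two-layer Bayesian network per pathway (latent transcription-factor
    node, latent target-gene states, dichotomized probe measurements)
    converts expression values into a log2 odds of transcription-factor
    activation, normalized to a 0-100 pathway activity score. Includes
    calibration of measurement-layer parameters on ground-truth samples,
    re-calibration when porting a gene panel to RT-qPCR with reference-gene
    delta-Cq normalization, healthy-tissue reference ranges with a
    95th-percentile abnormality threshold, multi-pathway patient reports,
    and a synthetic cohort generator with conflicting-gene and low-input
    dropout noise models for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
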