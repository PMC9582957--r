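Package: aacquant
Title: Quantification of Abdominal Aortic Calcification from Lateral Spine DEXA Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated scoring of abdominal aortic calcification (AAC) on
    lateral-spine dual-energy X-ray absorptiometry (DEXA) images using the
    24-point Kauppila scheme. Provides a synthetic phantom generator with
    exact ground truth, two localization front-ends (classical spine
    segmentation and learned per-vertebra box detection), spine-curve-based
    aortic region-of-interest extraction, rule-based and learned-regression
    calcification scoring with pipeline ensembling, an annotation consensus
    and agreement harness, and downstream cohort statistics: prevalence
    summaries, statin-adjusted LDL models, cystatin-C eGFR, per-SD biomarker
    associations, and a phenome-wide Cox proportional-hazards prognosis
    screen with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    survival,
    nnet,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
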