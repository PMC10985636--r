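Package: tpas
Title: Targeted Adversarial Training for Artifact-Robust MRI Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying rectal-artifact robustness of
    deep-learning prostate lesion detectors on biparametric MRI. Generates
    synthetic T2W/DWI/ADC phantom cohorts with graded rectal susceptibility
    artifacts, trains a miniature two-stage detection model (gland zone
    segmentation followed by five-channel lesion detection), crafts
    style-constrained bounded adversarial noise in the artifact pattern,
    performs targeted adversarial training with continuously regenerated
    proprietary adversarial samples, and evaluates paired models with
    patient-level ROC/AUC (DeLong test), lesion-level precision-recall/AUPRC
    (bootstrap comparison), Dice overlap, weighted kappa agreement, and
    artifact-severity subgroup reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
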