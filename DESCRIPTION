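Package: timascan
Title: Blood Monocyte GFAP Scanning for Brain Lesion Detection and Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical flow-cytometric gating and quantification of
    glial fibrillary acidic protein (GFAP)-carrying CD16+ blood monocytes,
    with downstream cohort statistics: derivation and validation of a
    diagnostic cutoff for brain-lesion detection (ROC, closest
    sensitivity-specificity criterion), survival dichotomization of
    glioblastoma patients by maximal median-survival difference, and
    classification of acute ischaemic stroke time courses by threshold
    exceedance. Includes a synthetic cytometry cohort simulator with known
    ground truth, minimal FCS 3.1 and CSV event-table input/output, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
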