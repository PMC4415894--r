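Package: gliotrack
Title: Longitudinal Quantification of Retinal Microgliosis and Optic Nerve Gliosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image-analysis pipeline linking early retinal and optic
    nerve head (ONH) microgliosis, measured in vivo from confocal scanning laser
    ophthalmoscopy (cSLO)-like fluorescence images, to late optic nerve
    degeneration measured as the non-axonal (glial) area fraction of nerve
    cross-sections. Provides intensity-threshold cell and soma segmentation with
    soma-area activation classification and radial-sector mapping, ONH circle
    counting and per-eye longitudinal timelines, automatic-threshold gliosis
    segmentation with vessel and meninges exclusion and damage categories, the
    cohort statistics layer (group summaries, unpaired t-test, Kruskal-Wallis,
    Spearman rank correlation with a permutation option, and a repeated-measures
    linear mixed model), and seeded synthetic phantoms (retina mosaics, nerve
    sections, longitudinal cohorts) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
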