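Package: neurocomp
Title: Moderated-Regression Mapping of Neural Compensation in Premanifest Neurodegeneration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a moderated-regression model of neural compensation in
    which behavioural performance is predicted by the interaction between
    structural disease load (regional brain volume as a fraction of
    intracranial volume) and an fMRI signal, applied voxelwise to task
    contrast maps and to seed-based resting-state connectivity features.
    Includes a synthetic cohort generator with known ground-truth parameters
    (disease-load-dependent atrophy, planted activity-by-load interactions on
    performance, planted resting-state coupling), volumetric image utilities
    (Gaussian smoothing, sphere extraction, a simplified first-level GLM),
    seed connectivity with nuisance regression and family-wise error control,
    equal-count conditioning-plot construction, and an end-to-end pipeline
    driver, so that every stage is testable by parameter recovery without any
    real subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
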