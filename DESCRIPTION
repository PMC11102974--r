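Package: biomechkit
Title: Neuromuscular and Biomechanical Assessment Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and morphometry pipelines for a comprehensive
    biomechanical characterization of an individual: maximal voluntary isometric
    contraction (MVIC) torque extraction from dynamometry, central activation
    ratio (CAR) from superimposed electrical stimulation trials, surface-EMG
    linear envelopes and the Rudolph co-contraction index (CCI) overall and per
    gait-cycle phase, muscle volume and maximal cross-sectional area from
    triangulated surface meshes, gait-cycle post-processing (mass/body-weight
    normalization, 101-point cycle grid, sagittal range of motion, walking
    speed, joint contact force peaks, permutation-based point-wise group
    comparison), cohort summary tables, and seedable synthetic-data generators
    with known ground truth for every input modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
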