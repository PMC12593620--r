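Package: redoxmap
Title: Quantitative Ratiometric Redox Imaging of roGFP-Expressing Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for excitation-ratiometric redox
    imaging with the redox-sensitive green fluorescent protein roGFP.
    Two-channel fluorescence fields (740 nm and 910 nm two-photon excitation)
    are converted to ratio images, somatic regions of interest are detected
    and averaged, ratios are calibrated to relative degrees of sensor
    oxidation (OxD) from fully oxidized and fully reduced endpoint
    recordings, and per-neuron OxD tables are screened (intactness range,
    ROUT outlier removal), aggregated at the cell and tissue-slice level and
    compared by two-way ANOVA with Holm-Sidak pairwise contrasts. A
    correlative-microscopy stage re-identifies imaged fields by bleach-mark
    registration, classifies nuclei by immunolabel intensity and compares
    per-slice normalized ratios between expression classes. A seeded
    synthetic-data generator renders realistic photon-limited image stacks
    with known ground truth so the whole pipeline is testable without
    acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    tiff,
    mclust,
    car,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
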