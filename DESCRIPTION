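Package: hemoquant
Title: Quantification of Hemocyte Endolysosomal Morphometry and Phagosome
    Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of phagocyte (Drosophila hemocyte)
    cell-based and organism-based assays from multi-channel fluorescence
    z-stacks and tabular cohort data: morphometric indices (occupied volume
    index, occupied area index, lysosomal aggregation, vesicle diameter
    ratio), Pearson colocalization over cell masks, time-lapse phagosome
    maturation scoring (docking time, pHrodo intensity ramps, FYVE coat
    prevalence), in vivo bacteria counting, median lifespan and colony
    forming unit estimation, together with the statistical comparisons used
    for these assays (one-way and two-way ANOVA with Bonferroni post hoc
    tests, exact Mann-Whitney tests). A ground-truthed synthetic scene
    generator produces calibrated image stacks and cohort tables so the
    entire pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
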