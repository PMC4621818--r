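Package: drylysim
Title: Whole-Plant Drought Phenotyping, Association Scans and
    Candidate-Gene Co-Localization for Asparagus Bean
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for genotypic drought responses in
    asparagus bean (Vigna unguiculata ssp. sesquipedalis). Converts
    gravimetric lysimeter traces into whole-plant physiology (daily
    transpiration, biomass gain, water-use efficiency, weight- and
    VPD-normalized transpiration), fits the segmented midday-transpiration
    versus soil-water model (E_max, critical soil water content, decline
    slope), implements ordinal drought scoring scales and cross-year trait
    correlations, runs marker-trait association scans under fixed-effect
    (Q) and mixed (Q + kinship) models, applies quantile-normalization and
    fold-change/FDR differential-expression filtering to array intensity
    matrices, and selects candidate genes by co-localizing differentially
    expressed genes with significant SNPs through genetic-map and
    ortholog-physical distance. A synthetic-data generator with known
    ground truth emulates every input design and backs the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
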