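Package: cfqct
Title: Quantitative CT of Airway Disease and Air Trapping in Early Cystic Fibrosis Lung Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative chest CT analysis of mild cystic fibrosis
    lung disease, exercised end-to-end on synthetic digital phantoms. The
    package generates tapering airway-tree phantoms and paired
    inspiratory/expiratory lung volumes with known ground truth, measures
    airway geometry (total diameter, wall thickness, lumen area, wall
    percentage) on orthogonal cross-sections by full-width-half-maximum ray
    casting, computes a tapering-based bronchiectasis index, derives paired
    air-trapping metrics (RVC856-950, E/I MLA and nested patient-specific
    defect percentages A1-A3) per lobe, simulates balanced longitudinal lobar
    cohorts, and fits the robust linear and beta mixed-effects models that
    link airway structure to air trapping cross-sectionally and
    longitudinally. A config-driven pipeline orchestrates phantom generation,
    measurement, trapping quantification and statistics into reproducible,
    seed-deterministic runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    lme4,
    lmerTest,
    glmmTMB,
    stats,
    utils,
    tools,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
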