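Package: pednorm
Title: Individualized Normative Brain Volumetry for Paediatric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Age-referenced regional brain volumetry for paediatric
    neuroimaging. Builds per-age-year normative references of total
    intracranial volume (TICV) corrected regional volumes from large
    healthy cohorts, estimates developmental age curves with annual
    percentage rate (APR) change, and classifies individual patients as
    having low or normal regional volume via Z-scores against age-matched
    norms with Benjamini-Hochberg false discovery rate control. Supports
    lesion-aware extraction: focal lesion masks are applied both to the
    patient and, symmetrically, to every control when building that
    patient's matched norms. Includes a synthetic-data module (tabular
    cohorts, voxel phantoms in NIfTI, cognitive batteries with known
    factor structure) for validation with known ground truth, plus
    exploratory-factor-analysis reduction of neuropsychological batteries
    and group-comparison stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
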