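Package: parotidbp
Title: Artificial Base Plans for Spatially Varying Parotid Dose Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for imposing spatially varying dose constraints on the
    contralateral parotid gland in head-and-neck radiotherapy planning.
    Partitions the gland into 18 equal-volume subsegments ranked by relative
    importance, synthesizes importance-scaled artificial base-plan dose
    distributions (the BP_10/BP_20/BP_30/BP_20,5/BP_top5 family), derives the
    associated optimizer constraint values, evaluates subsegment dosimetry
    (mean doses, DVH, V98, overlap, distances, paired tests), and predicts
    stimulated saliva output at one year after radiotherapy with a Hill
    dose-response ensemble. Includes DICOM RT-STRUCT/RT-DOSE reading and
    writing, a synthetic head-and-neck phantom generator, and a demonstration
    fluence-map optimizer showing how a loaded base plan steers dose away
    from high-importance subsegments at matched target coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    minpack.lm,
    generics,
    Matrix
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
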