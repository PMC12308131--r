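Package: lpftraj
Title: Lesion Parenchymal Fraction Modelling of Multiple Sclerosis Disease
    Course
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying multiple sclerosis disease course with
    the lesion parenchymal fraction (LPF): the ratio of regional T2 lesion
    volume to regional parenchymal volume, computed in the cervical cord,
    infratentorial and cerebral compartments of a topographical model of
    neurological reserve.  Provides a longitudinal synthetic-cohort
    generator, schema validation and scanner-harmonization checks for
    clinical and MRI visit tables, window-based temporal matching of
    clinical and imaging streams with directional imputation,
    percentile-scaled feature construction, leave-one-patient-out linear
    models decoding the expanded disability status scale (EDSS),
    relapse-free progression phenotyping, and four-panel per-patient
    trajectory visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    graphics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
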