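Package: ucsalign
Title: Single-Point Coordinate Superposition of Serial Dental Arch Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Superimposes serial intraoral-scanner surface models (STL) of the
    maxillary and mandibular arches using a single landmark expressed in a
    shared universal coordinate system, and quantifies orthodontic tooth
    movement between time points: buccolingual and mesiodistal translation,
    intrusion/extrusion, rotation in the occlusal plane, and arch expansion.
    Includes the full measurement-reliability toolkit used to validate such
    protocols (ICC(2,1) with 95% confidence intervals, Dahlberg's error,
    Bland-Altman limits of agreement, paired t-tests, and systematic-error
    gates), plus a synthetic arch generator with known ground-truth movements
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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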