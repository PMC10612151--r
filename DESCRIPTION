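Package: fusiform
Title: Intersecting-Circle Geometry for Fusiform Excision Design and
    Wound-Length Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form geometry of the equal-diameter intersecting-circle
    ("fusiform circle") model of fusiform (so-called elliptical) skin
    excision: apical inner/tangent/central angle relations, circular-arc
    radius and arc length, vertex push-out distance, dimensionless design
    curves, and numeric inversion for incision design. Includes the
    photographic scale/reference-object correction used to compare designed
    and healed incision lengths, a cohort analysis pipeline (per-site
    summaries, paired comparisons of designed length and designed arc
    against the postoperative incision), a seeded synthetic-cohort
    generator for end-to-end validation, printable SVG incision templates,
    and ggplot2 visualisations.
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
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
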