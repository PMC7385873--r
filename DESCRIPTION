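Package: iclcentr
Title: Centration Analysis of the EVO-ICL Central Hole in Anterior-Segment Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, segments and analyses en-face anterior-segment images of
    eyes implanted with a central-hole posterior-chamber phakic lens (EVO-ICL).
    Provides a seeded synthetic-cohort generator and slit-lamp-like renderer,
    direct least-squares ellipse fitting and detectors for the limbus, pupil and
    the 360-micrometre central hole, white-to-white based pixel-to-millimetre
    calibration, signed nasal/superior centration coordinates with quadrant
    classification, and cohort statistics (paired Wilcoxon signed-rank tests,
    Spearman rank correlations, kappa-angle relationships) with tidy accessors
    and ggplot2 graphics.
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
    generics,
    readr,
    stats,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
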