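Package: cosawave
Title: Sliding-Filament Waveform Variables and Centriole-Orientation
    Morphometry for Mammalian Sperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the mammalian sperm neck and flagellum:
    sliding-filament waveform variables (average amplitude, interfilament
    sliding and signed curvature of an arclength-parametrized centerline),
    centriole orientation-based sperm analysis (COSA) bend classification,
    signed nanometric neck-deformation metrics from landmark tables and
    localization point clouds (rod sliding, 50%-intensity-peak extents,
    proximal-centriole rocking and lateral shift, head-neck kink, segmented
    column displacement), and the accompanying statistical layer (Pearson
    correlation with regression, two-sample t tests, and exploratory factor
    analysis with KMO, Bartlett's sphericity and varimax rotation). Includes a
    seeded synthetic-specimen generator with known ground truth, image
    rasterization and automated centerline tracing, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    yaml,
    jsonlite,
    igraph,
    generics,
    pracma,
    tiff,
    png,
    EBImage,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
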