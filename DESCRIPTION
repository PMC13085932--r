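Package: soymapr
Title: Phenology-Driven Soybean Mapping from Multispectral Reflectance Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for mapping soybean from Sentinel-2-style multiband surface
    reflectance time series: ten-day median compositing with linear gap
    filling, a vegetation-index formulary covering red-edge and
    shortwave-infrared composites, Jeffries-Matusita class separability
    analysis for optimal time-window and feature selection, combinatorial
    construction of composite indices such as the soybean identification
    index built from the second red-edge band, the first shortwave-infrared
    band and the enhanced vegetation index, and an automatic threshold
    classifier with confusion-matrix accuracy assessment. A synthetic scene
    generator emulating soybean and corn canopy phenology lets the whole
    pipeline be exercised without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
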