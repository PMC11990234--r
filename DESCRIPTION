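Package: fnimenu
Title: Egg Substitution Modeling and Food Nutrient Index Scoring for
    Exemplary Menus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the partial substitution of one boiled egg (44 g) for a
    protein-source food in multi-day exemplary menus, scores micronutrient
    quality with the Food Nutrient Index (FNI) against adolescent (14-18 y)
    Dietary Reference Intakes, estimates daily menu cost from as-consumed
    USD/100 g prices, and compares conditions with Bonferroni-adjusted
    t-tests. Ships transcribed daily nutrient totals and daily prices for
    four seven-day exemplary menus (Healthy U.S.-Style, DASH, Harvard,
    Healthy Vegetarian), plus a seeded synthetic menu generator so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
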