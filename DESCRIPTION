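Package: cfrlp
Title: Complementary Feeding Recommendations by Linear Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify problem nutrients in infant-and-young-child
    complementary diets and to derive, systematically test and consolidate
    complementary feeding recommendations (CFR) with linear programming.
    Processes 24-hour dietary recalls into weekly diet-model parameters
    (median consumer portions, percentile-based serving and gram bounds),
    solves nutritionally-best and per-nutrient minimized/maximized 7-day
    diet models with a fixed breast-milk term, classifies absolute and
    partial problem nutrients against Recommended Nutrient Intakes (RNI),
    screens candidate recommendations, searches all candidate combinations
    under a worst-case population-adequacy criterion, and consolidates
    age-specific recommendations across age bands. A synthetic dietary
    survey generator with plantable nutrient gaps provides fully
    reproducible test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
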