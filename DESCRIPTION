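Package: enzlim
Title: Ecoenzymatic Stoichiometry and Microbial Nutrient Limitation in Lake Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Vector analysis of extracellular enzyme activities
    (beta-glucosidase, cellobiohydrolase, N-acetylglucosaminidase, leucine
    aminopeptidase, alkaline phosphatase) to quantify microbial carbon,
    nitrogen and phosphorus limitation in lake-sediment surveys, together
    with the statistical layer such surveys rely on: Redfield-ratio water
    classification, element-cycle distance matrices, Bray-Curtis community
    dissimilarity, Mantel permutation tests (with exact enumeration for
    small surveys), Pearson/OLS/quadratic screens and AIC stepwise predictor
    selection. A seeded synthetic saline-lake survey generator with known
    effect structure makes the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
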