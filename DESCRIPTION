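Package: livevuln
Title: Vulnerability of Livestock-Based Food Security to Climate and
    Population Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: National-scale composite vulnerability analysis for
    livestock-based food security under projected climate change and
    population growth.  Raw country indicators are min-max scaled,
    reduced to one representative indicator per category by Spearman
    rank correlation, and composed into sensitivity, exposure and
    adaptive-capacity indices; vulnerability is scored under additive
    and multiplicative models with climate-only and population-only
    scenario variants, population-weighted group summaries, and a
    441-combination sensitivity-grid robustness analysis.  Includes a
    seeded synthetic-nation generator with known latent structure for
    validation, and the published index scores of the 30 most- and
    least-vulnerable nations as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
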