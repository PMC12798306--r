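Package: bisim
Title: Microsimulation of Basic Income Effects on Adult Mental and Physical Health
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for estimating the population health
    effects of Basic Income schemes in the UK. Generates seeded synthetic
    household cross-sections and balanced panels with known income-health
    structure, runs a simplified static tax-benefit calculator (baseline system
    and three Basic Income reforms), estimates within-between (Mundlak) panel
    models of income on SF-12 mental and physical component scores with
    clustered bootstrap confidence intervals, forecasts cases of depressive
    disorder and physical health problems prevented, and values the gains as
    SF-6D utility changes, QALYs, willingness-to-pay value, years of life
    gained, and NHS and societal cost savings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    arrow
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
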