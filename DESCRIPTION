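Package: cropeval
Title: Comprehensive Benefit Evaluation of Intercropping Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comprehensive evaluation of intercropping field
    trials with a medicinal crop: a TOPSIS multi-criteria benefit index
    supporting benefit, cost and interval criteria (including an interval
    transformation for soil pH against an optimum growth range), derived
    agronomic and quality traits, treatment-versus-control effect summaries
    with significance flags, a weighted disease severity index, Pearson
    correlation screening, alpha-diversity and Bray-Curtis community metrics,
    and a seeded synthetic-trial generator that mirrors a two-region,
    eight-treatment strip-intercropping design so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
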