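Package: clptel
Title: Biotelemetry-Enhanced Analysis of Murine Sepsis Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing biotelemetry-enhanced cecal
    ligation and puncture (CLP) sepsis experiments in mice. Simulates
    post-operative heart-rate and core-temperature traces, detects acute
    physiologic deterioration by validated conjunctive criteria (a 10 percent
    heart-rate drop from peak together with a 10 percent fall of core
    temperature toward a 25 degree Celsius floor), characterises the
    variability of time-to-criteria with hourly capture windows (exact McNemar
    comparisons, binomial confidence intervals, seasonal stratification), and
    runs a decision-analytic cost-equivalency model quantifying the animals
    spared by physiologic enrollment relative to fixed-time-point designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
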