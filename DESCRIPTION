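Package: tomtrans
Title: Daily Transpiration Modelling and Irrigation Evaluation for
    Substrate-Grown Greenhouse Tomato
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing water use of tomato grown in coconut-coir
    substrate under a Venlo-type greenhouse. Extracts daily transpiration
    from morning weighing records by mass balance, builds daily leaf area
    index from periodic leaf measurements by shape-preserving piecewise
    cubic Hermite interpolation, screens micrometeorological drivers by
    correlation and path analysis, fits segmented multivariate
    daily-transpiration models by Levenberg-Marquardt damped least squares,
    evaluates models with MAE, RMSE, MRE and Nash-Sutcliffe efficiency, and
    ranks deficit-irrigation treatments by TOPSIS over yield, water use
    efficiency and fruit-quality indicators. A seeded synthetic-data
    generator reproduces the statistical structure of the greenhouse
    microclimate and weighing protocol so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
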