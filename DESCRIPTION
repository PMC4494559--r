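Package: bariCEA
Title: Cost-Effectiveness Modelling of Adolescent Bariatric Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-state ('alive'/'dead') Markov cohort model for the
    cost-effectiveness of bariatric surgery in severely obese adolescents.
    BMI reductions after surgery, with partial weight regain, drive annual
    medical-care savings, health-related quality of life and mortality;
    the model accumulates discounted costs and quality-adjusted life years
    (QALYs) and reports incremental cost-effectiveness ratios (ICERs) and
    net monetary benefit over 1-7+ year horizons. Includes calibration of
    the mortality and baseline-utility parameters to published life-year
    and QALY trajectories, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, one-way sensitivity sweeps,
    and generators for synthetic stand-ins of the underlying data sources
    (surgical cohort with billing lines, an HRQL/expenditure-vs-BMI
    survey, and a parametric life table).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
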