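Package: kinlearn
Title: Kinetic Modeling and Trial Statistics for Adaptive Learning Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses two-arm pre/post educational intervention
    trials in which vocabulary retention and learner anxiety follow first-order
    kinetic differential equations driven by a rule-based adaptive agent.
    Provides a tableau-generic explicit embedded Runge-Kutta pair with adaptive
    step-size control, exact closed-form solutions under piecewise-constant
    forcing, a synthetic longitudinal cohort generator, differential-evolution
    parameter estimation with student-level holdout validation and bootstrap
    confidence intervals, and the pre/post trial statistics stage (outlier
    screening, mean imputation, two-sample t tests, split-plot mixed ANOVA with
    partial eta squared, Cohen's d, Cronbach's alpha, subgroup analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
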