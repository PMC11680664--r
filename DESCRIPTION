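Package: forgetcurve
Title: Fitting and Classifying Memory Retention and Forgetting Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Meta-analytic tools for the study of memory retention over time.
    Fits five two-parameter retention functions (logarithmic, power,
    exponential in the square root of time, hyperbolic in the square root of
    time, linear) to (delay, proportion-remembered) series by least squares,
    classifies each data set into one of seven retention patterns (the five
    loss families plus stable and increasing) or removes it under a
    goodness-of-fit trimming rule, summarizes pattern prevalence weighted by
    the amount of data, and relates coded study characteristics to patterns
    via correlation screening, one-way ANOVA with Tukey comparisons,
    one-vs-rest logistic regression, and a gain-ratio decision tree. A
    synthetic-corpus generator with known generating curves and planted
    covariate associations makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
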