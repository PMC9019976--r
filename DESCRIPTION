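Package: copriss
Title: Co-Primary Sample Size and Blinded Re-Estimation for Comparative
    Diagnostic Accuracy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sample size calculation for comparative diagnostic accuracy
    trials in which sensitivity and specificity are co-primary endpoints
    evaluated by an Intersection-Union test. Implements the conventional
    (maximum-based) calculation and an optimal calculation that splits the
    overall power between the two endpoints so that the endpoint-specific
    total sample sizes coincide, for both unpaired and paired designs.
    Provides blinded interim estimation of nuisance parameters (prevalence
    and, in the paired design, the discordant test-result proportions) with
    sample size re-estimation, score and Tango-type confidence intervals for
    differences of proportions, generators for correlated paired binary test
    data, and a Monte-Carlo engine for operating characteristics of fixed
    versus adaptive designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    jsonlite,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
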