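Package: rollscore
Title: Rolling-Weights Estimation of Age-Varying Polygenic Score Effects
Version: 0.1.0
Authors@R:
    person("Analysis", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Estimates how the effect of a polygenic score on a quantitative
    trait varies across a continuous moderator (age) in family-structured
    longitudinal data. For each integer focus age, observations are weighted
    with a three-step kernel (shoulder kernel, min-max scaling, decay
    exponent) and a weighted linear mixed model with a family random effect
    is fitted; confidence intervals come from a family-block bootstrap.
    Includes a per-wave Generalized Partial Credit Model (IRT) stage that
    scores ordinal item responses into relative latent trait scores, and a
    synthetic-data generator for family-structured repeated measures with a
    known age-varying genetic effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lme4
Config/testthat/edition: 3
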