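Package: chasemetrics
Title: Within-Session Chasing Metrics from Online Gambling Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying within-session chasing (continuing or
    intensifying play after wins or losses) in round-level player-tracking
    logs from fast online gambling games. Provides a stochastic simulator of
    a Mystery-Arena-style dice game and of player cohorts with controllable
    stopping, staking and speed-of-play effects; readers, validators and
    break-based resegmentation for tracking logs; the three per-player
    chasing indicators (relative likelihood of stopping, stake change, and
    standardized first-column response times) with their inclusion filters;
    and the accompanying statistical battery (Welch and paired t-tests,
    Holm-Bonferroni adjustment, Hedges' g, JZS Bayes factors with a Cauchy
    prior, 2x2 mixed ANOVA with generalized eta squared, and within-subject
    confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
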