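Package: fledgelink
Title: Dyadic Biologging Analysis of Post-Fledging Parental Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying post-fledging parental care in colonial
    waterbirds from dyadic GPS tracking, tri-axial acceleration and
    colour-ring resighting data. Simulates family tracking data with known
    ground truth; estimates chick age from eighth-primary length via Gompertz
    growth-curve inversion; applies a visual sex-assignment decision rule;
    segments trajectories into flight bouts and detects autumn-migration
    departure days and moments; links chick and parent tracks by nearest
    timestamp and scores contact moments at configurable distance thresholds;
    classifies behaviour (including chick begging) from fixed-length
    acceleration segments with a random-forest ensemble evaluated by pooled
    F-measures; and fits the feeding-observation, contact and
    distance-to-nest models (Poisson GLM, linear model, binomial and Gamma
    GLMMs with correlated random intercept and age slope) compared by
    small-sample-corrected AIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    ranger,
    lme4,
    e1071,
    jsonlite,
    yaml,
    tibble
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
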