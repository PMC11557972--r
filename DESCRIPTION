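Package: apisomnia
Title: Circadian Sleep-Rhythm Analysis for Caged Honey Bee Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing hourly ethogram-style sleep observations of
    caged honey bees under constant-light (LL), constant-dark (DD), and 12:12
    light:dark (LD) regimes. Provides a synthetic experiment generator with
    condition-specific circadian structure, validated CSV ingestion, circadian
    period estimation by harmonic regression over a dense period grid,
    alignment-to-control metrics (day-4 signed and absolute AUC of paired curve
    differences, midpoint-peak distance), sleep-disruptor summaries (cage light
    gradient, lower-half position preference, disturbance-contact rates),
    repeated-measures mixed models, nonparametric group comparisons, and a
    reproducible pipeline with figure output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
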