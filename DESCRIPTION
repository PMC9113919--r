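Package: speedscale
Title: Speed and Scale Channel Analysis of Ocular Following Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the human visual system estimates stimulus
    speed from broadband motion input, built around short-latency ocular
    following responses. The package generates drifting-grating and
    motion-cloud stimulus descriptions and their motion-energy envelopes in
    log-frequency space, preprocesses eye-position recordings into clean
    velocity traces and windowed response statistics, fits quadric tuning
    surfaces with speed/scale axis angles and a separability index, compares
    pattern-driven tracking against linear component predictions (nonlinearity
    ratios, separation times, bootstrap tests), and implements a dynamic
    probabilistic channel model with excitatory-inhibitory interactions in
    speed-scale coordinates, Bayesian decoding over log speed, maximum
    likelihood fitting, and AIC model comparison. A synthetic cohort generator
    reproduces the statistical structure the analyses assume so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
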