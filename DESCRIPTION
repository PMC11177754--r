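Package: pressorloop
Title: Closed-Loop Norepinephrine Infusion Control of Arterial Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a computer-controlled closed-loop norepinephrine (NE)
    infusion system that titrates NE every 2 seconds to hold mean arterial
    pressure (MAP) at a target during anesthesia-induced hypotension. The
    control law combines an asymmetric nonlinear error transformer, a
    parallel-form PID controller, and an output limiter with a hypertensive
    shut-off. A calibrated virtual-dog pharmacodynamic plant (sigmoid Emax
    statics, first-order dynamics, transport dead time, measurement noise,
    log-normal inter-animal variability) replays the study protocol, and
    Varvel-style performance metrics (MDPE, MDAPE, wobble, divergence,
    time-in-range) evaluate each trial. Includes first-order-plus-dead-time
    step-response fitting with Chien-Hrones-Reswick gain rules, CSV trial
    logs, ggplot2 visualisations, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
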