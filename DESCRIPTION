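Package: myohmi
Title: Single-Channel Surface-EMG Human-Machine Interface Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end simulated myoelectric human-machine interface:
    seeded synthetic single-channel surface electromyography (sEMG) sessions
    with labeled isometric contraction bursts; a first-order digital low-pass
    filter derived by difference equation, with DFT spectrum analysis to
    locate dominant interference and tune the cutoff frequency; burst
    segmentation, feature extraction and a one-hidden-layer softmax
    multilayer perceptron trained by Adam on one-hot contraction classes; an
    eight-state Mealy machine mapping classified contractions to Cartesian
    set-points; and a 3-DOF anthropomorphic manipulator model (forward and
    inverse kinematics, Euler-Lagrange dynamics) regulated by a PD+
    gravity-compensated controller under fixed-step Runge-Kutta integration.
    Includes an evaluation harness reproducing trajectory-following response
    times and penalty counts on scripted sessions.
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
    withr
Config/testthat/edition: 3
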