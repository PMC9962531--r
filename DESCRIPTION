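Package: pneumotex
Title: Simulation and Analysis of Textile Piezoresistive Respiration Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing a textile piezoresistive
    respiration-sensing chain: deterministic testing-machine stretch
    waveforms and stochastic human-breathing strain waveforms; a calibrated
    gauge-response model mapping elongation to sensor resistance with
    optional hysteresis and noise; a voltage-divider plus ADC acquisition
    model reconstructing resistance the way a microcontroller would; a
    slope-threshold breath detector with per-window counting and
    respiratory-pattern classification; textile characterisation formulas
    (surface mass, air permeability, thermal resistance, sensory
    coefficient); and end-to-end scenario runners with device-versus-reference
    agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
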