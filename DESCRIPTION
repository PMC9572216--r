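Package: insolemetry
Title: Plantar Pressure and Temperature Analytics for Smart Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software stack for force-sensitive-resistor (FSR) and NTC
    thermistor smart insoles: voltage-divider sensor calibration (ADC counts
    to resistance, force and temperature), exponential thermistor curve
    fitting, a delimited frame codec and trial logger for 24-channel
    multiplexed insole streams, a seeded synthetic walking/standing
    simulator with sensor hysteresis, vertical ground reaction force (vGRF)
    gait-cycle segmentation with 512-point resampling and ensemble
    statistics, interpolated plantar pressure and temperature maps on a
    parametric foot template, and battery-life budgeting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
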