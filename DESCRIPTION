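Package: vpcharts
Title: Variable-Parameters Memory-Type Control Charts for Multivariate
    Linear Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous monitoring of the mean and variability of
    multivariate multiple linear regression profiles with four memory-type
    control charts (Max-MEWMA, Max-MCUSUM, SS-EWMAe and SS-CUSUMe), under
    both fixed-parameters (FP) and adaptive variable-parameters (VP)
    sampling schemes. Includes Monte-Carlo calibration of upper control and
    warning limits to target in-control average run length, zero-state
    run-length and time-to-signal performance evaluation, a synthetic
    Phase-II sample-stream generator, and a Phase-II monitoring runner that
    produces decision tables and control-chart plots. Ships ready-made
    profile scenarios, including a healthcare application to thrombolysis
    delay-time monitoring in stroke care.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
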