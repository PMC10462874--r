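Package: phstatsim
Title: Closed-Loop Simulation of a pH-Stat Autotitrator for In Vitro Lipolysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and analysis toolkit for a syringe-pump
    pH-stat autotitrator. Couples an acid-base speciation model (charge-balance
    pH solver, strong-base dosing, first-order free-fatty-acid release
    kinetics) to a model of the instrument chain (pH-meter analog output,
    resistor-divider bias, 10-bit ADC quantization, lead-screw stepper volume
    discretization) and the firmware's feedback dosing loop. Includes the
    append-only microSD-style log format with a lossless parser, post-run
    analysis (cumulative NaOH volume, percent free fatty acids released,
    endpoint detection, rate-constant recovery), and packaged seedable
    scenarios (phosphate-buffer titration, olive-oil emulsion lipolysis) so
    the full closed loop is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
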