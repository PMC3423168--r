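Package: issf
Title: Periodic Step-Function Forcing of SBML Models for Circadian Simulation Protocols
Version: 0.1.0
Authors@R: person("ISSF", "Maintainers", email = "issf@example.org", role = c("aut", "cre"))
Description: Implements a six-parameter, numerically continuous periodic pulse
    waveform (the input signal step function) used to force parameters of
    ODE models of circadian clocks, together with machinery to inject the
    waveform into SBML models as MathML assignment rules, compose multiple
    signals, and run entrainment, photoperiod and phase-response-curve
    protocols with a built-in ODE simulator. Ships self-contained SBML
    fixtures (a Goodwin-type oscillator and an analytic accumulator model)
    so every protocol is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
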