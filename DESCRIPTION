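Package: betadbs
Title: Closed-Loop Deep Brain Stimulation in a Delayed STN-GPe Firing-Rate Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of beta-band oscillations in a delayed firing-rate model
    of the reciprocally coupled subthalamic nucleus (STN) and external globus
    pallidus (GPe), and of closed-loop deep brain stimulation (DBS) strategies
    acting on it. Provides a fixed-step integrator for delay differential
    equations, sigmoid population activations with equilibrium analysis,
    proportional and self-tuning (sigma-modification) adaptive controllers with
    beta-band biomarker drives, oscillation maps over coupling space, nonlinear
    frequency-response (Bode) profiles, biomarker filters and controller
    performance measures, identification of the GPe activation function and
    self-coupling from steady-state rate data, and a surrogate stimulation
    plant for exercising clinical-style adaptation scenarios (target changes,
    background beta fluctuation, electrode impedance drift).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
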