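Package: hnburst
Title: Bursting Driven by Persistent Sodium and Sodium-Potassium Pump
    Currents in Heartbeat Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based modelling and analysis of endogenous bursting
    in leech heartbeat (HN) interneurons driven by the interaction of the
    persistent sodium current (INaP) and the sodium-potassium pump current
    (Ipump). Provides a full Hodgkin-Huxley style "virtual hybrid neuron"
    simulator with dynamic-clamp style injected INaP and Ipump and
    intracellular sodium bookkeeping, a reduced two-variable
    (membrane potential, intracellular sodium) relaxation-oscillator model,
    burst detection and envelope statistics, low- versus high-amplitude
    regime classification with a Gaussian naive Bayes classifier,
    nullcline-based phase-plane analysis with knee points and slow-branch
    timing estimates, and an elitist evolutionary algorithm for fitting the
    reduced model to bursting summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
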