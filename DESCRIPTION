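Package: dualsine
Title: Single-Trial Excitatory and Inhibitory Conductance Estimation from
    Dual-Sinusoid Current-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simultaneous, time-resolved estimation of excitatory and
    inhibitory synaptic conductances from a single current-clamp trial in
    which the injected current is the sum of two high-frequency sinusoids.
    Narrow-band filtering and the analytic (Hilbert) signal give instantaneous
    complex impedances at the two stimulus frequencies; a closed-form circuit
    inversion yields the series (electrode) resistance and total membrane
    conductance over time, after phase-based estimation of the cell
    capacitance and optional compensation of pipette stray capacitance. The
    cleaned membrane potential and total conductance are then decomposed into
    excitatory and inhibitory components via the passive membrane equation.
    Includes ground-truth generators (short-term-depressing synaptic trains,
    step and network-like conductances, recording noise, wandering access
    resistance), a passive point-neuron simulator with an electrode model,
    and a passive dendritic cable simulator with somatic current- and
    voltage-clamp for validation against space-clamp-limited recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
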