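Package: padsim
Title: Conductance-Based Modelling of Primary Afferent Depolarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of primary afferent depolarization (PAD)
    in a Morris-Lecar-type conductance-based neuron model with a depolarizing
    GABA-A chloride conductance. Provides the single-compartment membrane
    model with optional partial sodium-channel inactivation, stimulus
    waveform generators (conductance steps, ramps and double-exponential
    synaptic waveforms; current steps), an adaptive-step integration and
    spike-classification engine, two-parameter region maps of PAD-induced
    spiking and PAD-mediated inhibition with boundary extraction, in-silico
    dynamic-clamp protocols (conductance titration, kinetics comparison,
    virtual sodium conductance, rheobase under GABA shunting, combined
    conductance/current inhibition assays), a three-compartment axon cable
    model of conduction block, and a synthetic virtual-neuron-population
    generator for proportion-of-spiking studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
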