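# padsim

Conductance-based modelling of **primary afferent depolarization (PAD)**.

Sensory axons keep intracellular chloride high, so activating their
GABA~A~ receptors *depolarizes* them (E_GABA ≈ −35 mV). That
depolarization normally *inhibits* spike transmission — through membrane
shunting and sodium-channel inactivation — yet under pathological
conditions (depolarized E_GABA, increased intrinsic excitability) the
same conductance can *trigger* spikes. `padsim` is for computational
neuroscientists and pain researchers who want to dissect this trade-off
quantitatively: when does PAD excite, when does it inhibit, and can it do
both at once?

## The model

A Morris–Lecar-type single compartment with a depolarizing GABA
conductance and partial sodium inactivation:

    C dV/dt = I_stim − g̅_Na m∞(V) [p·h + (1−p)] (V−E_Na)
              − g̅_K w (V−E_K) − g_leak (V−E_leak) − g_GABA(t) (V−E_GABA)

with `m∞(V) = 0.5[1 + tanh((V−β_m)/γ_m)]` instantaneous, and `w`
(recovery; midpoint `β_w` is the excitability dial) and `h` (slow sodium
inactivation acting on the fraction `p` of `g̅_Na`) relaxing as
`dx/dt = φ_x (x∞(V) − x)/τ_x(V)`, `τ_x(V) = 1/cosh((V−β_x)/(2γ_x))`.
Conductances applied to cells are capacitance-normalized (nS/pF;
1 nS/pF ≡ 1 mS/µF). On top of the membrane model the package provides:

* stimulus waveforms (steps, ramps, peak-normalized double-exponential
  synaptic conductances; current steps),
* a compiled adaptive-step simulation engine with spike detection and
  none/transient/repetitive classification,
* two-parameter region maps (E_GABA × β_w spiking; E_GABA × p
  inhibition) with boundary extraction by grid sweep + bisection,
* in-silico dynamic-clamp protocols: conductance titration, fast/slow/
  step/ramp kinetics comparison, virtual sodium conductance, rheobase
  under GABA shunting, combined conductance/current inhibition assays,
* a three-compartment unmyelinated-axon cable model of conduction block
  (d_lambda-rule discretization, banded stiff integration),
* a seeded synthetic virtual-neuron population for
  proportion-of-spiking-cells studies,
* a thin CLI (`inst/cli/pad.R`) and flat-config/CSV/JSON writers.

## Worked example

```r
library(padsim)

# Normal conditions: E_GABA = -35 mV, beta_w = -20 mV.
# A 2 nS/pF GABA step depolarizes but cannot spike the cell:
classify_trace(neuron_params(), conductance_step(2, -35))
#> <response_class> none - 0 spike(s) in window

# Raise excitability (beta_w -20 -> -10 mV, the 4-AP analog) and
# depolarize E_GABA to -20 mV: a fast synaptic waveform now fires it
hot <- neuron_params(beta_w = -10)
classify_trace(hot, synaptic_fast(2, -20))
#> <response_class> transient - 1 spike(s) in window

# Titrate the minimum conductance, as dynamic clamp would:
find_min_ggaba(hot, synaptic_fast(1, -20))
#> <titration_result> target: any  min g_bar: 1.50146484375 nS/pF  (resolution 0.01 nS/pF)
find_min_ggaba(hot, synaptic_slow(1, -20))
#> <titration_result> target: any  min g_bar: 3.0859375 nS/pF  (resolution 0.01 nS/pF)
```

The slow-onset waveform needs roughly twice the conductance — transient
spike initiation is sensitive to the *rate* of depolarization, which is
why diffuse, asynchronous GABA spillover rarely fires an afferent even
when an abrupt input would.

Inhibition survives excitability: with all sodium channels inactivatable
(`p = 1`), a 2 nS/pF GABA step raises the current threshold for spiking
(rheobase) markedly:

```r
rheobase(neuron_params(p = 1), g_bar = 0, e_rev = -35)  # 27.1 pA/pF
rheobase(neuron_params(p = 1), g_bar = 2, e_rev = -35)  # 50.4 pA/pF
```

See the vignette (`vignettes/pad-model.Rmd`) for the full model
description, region-map and cable workflows, and every numerical design
choice.

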