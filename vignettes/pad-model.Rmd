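---
title: "Modelling primary afferent depolarization: excitation, inhibition and conduction block"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling primary afferent depolarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The central terminals of primary afferent (sensory) fibers keep their
intracellular chloride concentration above electrochemical equilibrium, so
activating axonal GABA~A~ receptors *depolarizes* them (primary afferent
depolarization, PAD; chloride reversal near −35 mV). PAD normally
*inhibits* spike transmission, through membrane shunting and sodium-channel
inactivation, but under pathological conditions — a depolarizing shift of
E~GABA~, increased intrinsic excitability — the same conductance can
*elicit* spikes (dorsal root reflexes). `padsim` implements a minimal
biophysical model of this trade-off and the analysis protocols around it:
two-parameter region maps of spiking and inhibition, in-silico
dynamic-clamp assays, an axon cable model of conduction block, and a
synthetic virtual-neuron population.

## The membrane model

A single compartment obeys the current balance

$$C\frac{dV}{dt} = I_{stim}
 - \bar g_{Na}\, m_\infty(V)\,[p\,h + (1-p)]\,(V-E_{Na})
 - \bar g_K\, w\,(V-E_K)
 - g_{leak}(V-E_{leak})
 - g_{GABA}(t)\,(V-E_{GABA})$$

with instantaneous sodium activation
$m_\infty(V) = 0.5\,[1+\tanh((V-\beta_m)/\gamma_m)]$ and first-order gates

$$\frac{dx}{dt} = \phi_x\,\frac{x_\infty(V) - x}{\tau_x(V)}, \qquad
x_\infty(V) = 0.5\,[1+\tanh((V-\beta_x)/\gamma_x)], \qquad
\tau_x(V) = 1/\cosh\!\big(\tfrac{V-\beta_x}{2\gamma_x}\big)$$

for the recovery variable $w$ ($\beta_w, \gamma_w, \phi_w$) and the slow
sodium-inactivation gate $h$ ($\beta_h = -28$ mV, $\gamma_h = -14$ mV,
$\phi_h = 0.005$; $\gamma_h < 0$ so $h$ closes with depolarization). The
fraction $p \in [0,1]$ of sodium channels subject to inactivation is the
dial separating the plain three-current model ($p = 0$, where $h$ is
integrated but has no effect — the reduction is exact and tested) from the
inactivating variant used for the inhibition and conduction analyses.

Two parameters carry the biology:

* **$\beta_w$** — the midpoint of the recovery gate, the intrinsic
  excitability dial. $\beta_w \approx -20$ mV is the normal operating
  point; shifting it toward 0 mV (the "4-AP analog",
  `apply_4ap_analog()`, default +10 mV since no published shift value
  exists) reproduces injury- or 4-AP-induced hyperexcitability and moves
  the cell from no spiking through transient toward repetitive spiking.
* **$E_{GABA}$** — the chloride reversal potential; −35 mV normally,
  −20 mV under enhanced chloride loading.

### Parameter presets

| preset | distinguishing values | use |
|---|---|---|
| `default` | $C=2$ µF/cm², $\bar g_{Na}=\bar g_K=20$ mS/cm², $E_{Na}=50$, $E_K=-100$, $g_{leak}=2$, $E_{leak}=-70$ mV, $\beta_m=-1.2$, $\gamma_m=18$, $\gamma_w=10$ mV, $\phi_w=0.15$ | all region maps and protocols |
| `revised` | $g_{leak}=0.7$, $\bar g_K=30$ mS/cm² | higher GABA sensitivity (sub-1 nS/pF titration minima) matching dissociated-neuron measurements |
| `cable` | $\bar g_{Na}=\bar g_K=30$ mS/cm² | the multicompartment axon |

### Units

Internal computation uses mV, ms, µA/cm², mS/cm², µF/cm². Conductances
applied to cells are quoted capacitance-normalized (nS/pF), the scale on
which results are independent of cell size; since 1 nS/pF ≡ 1 mS/µF, the
conversion is `g[mS/cm²] = g[nS/pF] × C[µF/cm²]` (so 2 nS/pF ↔ 4 mS/cm² at
C = 2). Currents convert identically between pA/pF and µA/cm². The
conversion is exposed (`nspf_to_density()`) and tested rather than buried.

## Stimuli

`conductance_step()`, `conductance_ramp()` and `conductance_synaptic()`
generate the GABA conductance time courses; `current_step()` the
stimulating current. The synaptic waveform is the peak-normalized double
exponential $\bar g\,x\,(e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}})$ with
the *fast* preset (2/20 ms) standing for intrasynaptic receptor activation
and the *slow* preset (20/200 ms) for asynchronous activation of
extrasynaptic receptors by spilled-over GABA. Step and ramp hold durations
are not printed anywhere authoritative; the defaults (1000 ms hold, 500 ms
ramp rise) were chosen once so that "repetitive" spiking — sustained to
stimulus end — is unambiguous, and are configurable.

## Numerics

* **Integration** — `deSolve::lsoda` (adaptive-step, stiff-capable) over a
  compiled C right-hand side, with dense output interpolated onto a fixed
  0.05 ms grid so spike detection is decoupled from solver stepping.
  Default tolerances `rtol = 1e-6`, `atol = 1e-8`. The refinement
  contract — halving the output step or tightening tolerances 10× changes
  no classification and moves voltage samples by far less than 0.5 mV — is
  part of the test suite.
* **Initial conditions** — every trial starts from `resting_state()`, the
  most hyperpolarized root of the steady-state current equation on
  [−100, 0] mV (grid scan for a sign change, then bracketed root finding
  to 10⁻⁹). A grid scan is needed because strong regenerative
  conductances can create several fixed points.
* **Spike detection** — upward crossing of 0 mV, 2 ms refractory, plus a
  prominence criterion (peak ≥ 20 mV above the voltage 10 ms before the
  crossing). The prominence test is what prevents the strongly shunted
  plateau near E~GABA~ — which can sit above 0 mV for depolarized
  reversals — from being counted as spiking. No published detection
  criterion exists; these are declared defaults, and counts are invariant
  to thresholds anywhere in ±10 mV for full-height spikes.
* **Classification** — over the stimulus window (for synaptic waveforms:
  onset until decay below 5% of peak): *none* if no spike; *repetitive*
  if ≥ 3 spikes and the last falls in the final quarter of the window
  (so an onset burst is never "repetitive"); *transient* otherwise.

## Region maps and boundaries

`sweep_spiking_2d()` classifies the response to a conductance input over a
rectangular parameter grid (canonically E~GABA~ × β~w~, default steps 1 mV
and 0.5 mV), each cell simulated independently from rest — no state
carry-over, no hysteresis. Boundaries are extracted by scanning each grid
row for the class change and placing the boundary at the cell midpoint,
optionally sharpened by bisection of fresh simulations to 0.25 mV
(`extract_boundary(refine = TRUE)`). This grid-plus-bisection approach
replaces numerical continuation deliberately: it is reproducible with
elementary numerics and validated by refinement invariance (labels are
unchanged on refined grids and at tightened solver tolerances) rather than
by eigenvalue analysis. Bifurcation-type labelling of the boundaries is
out of scope.

`sweep_inhibition_2d()` maps PAD-mediated inhibition over (E~GABA~, p) at
β~w~ = 0: a current step must drive repetitive spiking on its own (checked;
by default the amplitude is auto-set to 1.5× the repetitive-spiking
threshold found by bisection), and a 400 ms conductance step is interposed
300 ms into it. Two criteria are reported per cell: *stopped* — no spikes
in the final 50% of the overlap — and the weaker *reduced* — overlap spike
rate at most half the current-alone rate in the matched window. Cells
where the current alone is not repetitive (possible at large p through
inactivation accumulation) carry `NA` flags rather than a silent guess.

## Protocol notes and design choices

* **Titration** (`find_min_ggaba()`): bisection on [0, 10] nS/pF to
  0.01 nS/pF. Spiking is *not* monotone in amplitude — strong conductance
  shunts spiking away — so a silent upper bound triggers a documented
  fallback (coarse downward scan, `non_monotone` flag, bisection of the
  onset below the recovered spiking amplitude).
* **Kinetics comparison** (`compare_kinetics()`): in transient-regime
  cells the slow waveform needs ~50% more conductance than the fast one
  and a slow ramp at 2.5× the step minimum still fails — the signature of
  rate-sensitive spike initiation. In repetitive-regime cells the slow,
  step and ramp minima coincide exactly (amplitude-only initiation) while
  the brief fast waveform sits within ~10%; the `rate_sensitive` flag
  therefore uses a 10% relative margin.
* **Virtual sodium** (`add_virtual_sodium()`): a non-inactivating
  conductance added to the sodium current, defaulting to the model's own
  activation curve with independent density. The published formulation of
  the experimental virtual conductance is not available, so this is a
  declared minimal stand-in. With the default steep, high-threshold
  activation, no density destabilizes the leak-anchored rest without
  creating a depolarized plateau; the hyperexcitability demonstration
  therefore uses the overridable kinetics with a *persistent* sodium
  conductance activating near rest (midpoint −60 mV, slope 10 mV), where
  0.3 nS/pF plus the 4-AP analog yields sustained spontaneous repetitive
  spiking — the same density scale as the dynamic-clamp experiments. Since
  the model is deterministic (no channel noise), spontaneity is probed by
  inserting the conductance into the cell resting *without* it, exactly
  as dynamic clamp does.
* **Rheobase** (`rheobase()`): minimum current-step amplitude evoking ≥ 1
  spike while the conductance step is active (conductance 100–500 ms,
  current 300–700 ms; spikes counted in the 200 ms overlap, so an onset
  spike at the conductance step is never counted). The headline property —
  rheobase rising with ḡ~GABA~ at both reversal potentials, with E~GABA~
  secondary — is evaluated with `p = 1` (all sodium channels
  inactivatable, as in a real membrane) at ḡ~GABA~ ∈ {0, 2, 4} nS/pF.
  This choice is deliberate: at E~GABA~ = −20 mV a *weak* conductance
  (≈1 nS/pF) is net excitatory in this model and dips rheobase by a few
  percent; shunting dominates from ~2 nS/pF upward, which is also the
  regime the inhibition analyses emphasize.

## The axon cable

`cable_params()`/`build_cable()` define three serially coupled 1 mm
compartments of a 1 µm unmyelinated axon (axial resistivity 150 Ω·cm,
membrane as the `cable` preset). Discretization follows the d_lambda rule:
segments no longer than `d_lambda` (default 0.01) times the 100 Hz space
constant $\lambda = \sqrt{d/(4\pi f R_a C_m)}$ ≈ 163 µm, giving 615
segments per compartment at the default; an odd count guarantees a
midpoint. Axial coupling between segment centres is ohmic, expressed as a
conductance density over the segment membrane so that coupling currents
share the membrane-equation units; ends are sealed. The interleaved state
ordering (V, w, h per segment) keeps the Jacobian banded (half-bandwidth
3), which the same `lsoda` integrator exploits. Test pulses are specified
as absolute current (nA) into the leftmost segment — a density
specification would dilute with segment count — with amplitude 2× the
propagation threshold found by bisection (pulse parameters are not
printed anywhere authoritative; 1 ms width is the declared default).

`conduction_assay()` reports, per pulse, whether the evoked spike reached
the left and right compartment midpoints (with latencies), and attributes
middle-compartment spikes without a preceding left-midpoint wavefront to
PAD itself, with flags for bidirectional propagation; collisions inside
the attribution window are flagged ambiguous rather than silently
classified. The four qualitative conduction regimes — pure-shunt block at
E~GABA~ = −35 mV, a bidirectionally propagating PAD-evoked spike
coexisting with block at −20 mV, inactivation-dependent block at modest
conductance, and progressive train failure under weak PAD — are each
located by searching a coarse (ḡ~GABA~, p) grid, because the specific
parameter combinations behind the published examples are unrecoverable.
Unit and acceptance tests run the cable at `d_lambda` 0.1–0.05 (63–123
segments per compartment), where conduction latencies agree with the
default discretization to within 5%; the full 0.01 rule remains the
construction default.

## The synthetic population

`population_spec()`/`sample_population()` generate a heterogeneous virtual
population standing in for dissociated DRG neurons: β~w~ drawn from a
truncated normal (mean −20 mV, SD 4 mV, bounds [−30, −5] mV — centred on
the normal operating point and spanning the no-spiking/transient/
repetitive region structure), with optional lognormal multipliers on
g~leak~ and ḡ~K~ (off by default). These defaults are a plausible spread
of excitability, chosen once; **no claim is made that they match the real
DRG distribution**, which is unidentifiable from published summary
proportions. Consequently the population results are read as *orderings*
(the combined E~GABA~ shift + excitability shift recruits at least every
cell either single change recruits, cell by cell — a stronger statement
than the proportion ordering), never as fits to experimental proportions.
All randomness lives in the seeded sampler; the titration protocol over
the condition matrix is deterministic, so (spec, seed) reproduces results
bit for bit.

What the generator does *not* emulate: channel noise, cell-size variation
(results are capacitance-normalized away from it), correlated parameter
covariation, chloride-concentration dynamics, and any injury-specific
parameter mapping beyond the β~w~ shift. Passing tests therefore show the
model's mechanism logic under a declared heterogeneity, not DRG population
statistics.

## Problem sizes

The test suite runs the region analyses on coarsened grids (2.5 mV × 1 mV
steps and 5 × 0.25 for the inhibition plane) and the cable at
`d_lambda = 0.1`; these sizes were chosen so the full suite completes in a
few minutes while every qualitative contrast retains a safety margin of
several grid cells. `scripts/acceptance.R` recomputes the headline
titration on the full 46 × 51 grid at 0.01 nS/pF resolution.

## Known limitations

* Deterministic model: no stochastic channel gating or synaptic noise, so
  "spontaneous" activity must be probed by perturbation or insertion.
* Chloride concentration is fixed: no activity-dependent E~GABA~ shift or
  chloride depletion during PAD.
* No temperature dependence; gating rates are those of the
  room-temperature formulation.
* The virtual sodium stand-in is declared, not derived from the original
  dynamic-clamp formulation.
* The cable has no branch points, no myelin, and no chloride diffusion;
  it models continuous conduction in a straight unmyelinated segment.
* Boundary extraction assumes the region border crosses each grid row at
  most once where it is refined; the up-set sanity check
  (`check_upset()`) reports violations instead of hiding them.
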