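---
title: "Multiscale circuit models of the C. elegans motor system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale circuit models of the C. elegans motor system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcircuit)
```

`wormcircuit` generates executable network models of the *C. elegans*
nervous system and body-wall musculature from connectome wiring tables, at
four selectable levels of biophysical detail, and simulates them with a
built-in fixed-step integrator. This vignette is the package's account of
the science: the model families and their assumptions, the parameters that
matter, the numerical choices, and what the shipped tests do and do not
establish.

## From wiring table to network model

A connectome here is three tables: cells, directed chemical connections
(with anatomical contact counts and a neurotransmitter annotation), and
undirected gap-junction pairs. Readers are provided for the two public
spreadsheet layouts in circulation; both feed one internal representation.
Two deliberately simple rules resolve anatomy into model synapses:

* **Weight rule.** The conductance of a connection is the product of a
  per-contact baseline conductance and the number of anatomical contacts,
  `g = n × g_baseline`, with `g_baseline` = 0.01 nS per contact for both
  chemical synapses and gap junctions. Individual weights can be overridden
  (`override_weight()`) to probe sensitivity.
* **Polarity rule.** A chemical connection is inhibitory exactly when the
  presynaptic cell transmits GABA, and excitatory otherwise — including
  when the transmitter is unknown. This is a first approximation: real
  polarity depends on the postsynaptic receptor, which is not annotated in
  the wiring tables. The reader takes per-row transmitter annotations where
  the dialect provides them and falls back to the presynaptic cell's
  annotation otherwise.

Reader edge cases are resolved as follows: self-connections are dropped
with a warning (they would make the pair-weight rule ill-defined and the
circuits modelled here contain none); duplicate rows for the same ordered
pair are summed (contact counts are counts); mirrored duplicate rows for
gap junctions collapse to one entry per unordered pair.

## Cell and synapse model families

The four parameter sets span abstraction levels, so the same wiring can be
instantiated as anything from a spiking point-neuron caricature to a
conductance-based model with calcium dynamics:

* **A** — leaky integrate-and-fire cells; *every* connection, including
  gap-junction entries, becomes a spike-triggered synapse. The gap-to-spike
  conversion keeps the weight unchanged (an identity mapping; nothing in
  the level definition fixes a conversion factor) and emits one directed
  synapse per direction, preserving the junction's symmetry.
* **B** — LIF cells plus a leaky spike accumulator
  (`τ_a da/dt = −a`, `a ← a + Δ` per spike) as a firing-rate proxy, and
  true electrical gap junctions. The proxy is a *readout only*: nothing in
  the level definition says it feeds back onto the membrane, so it does
  not.
* **C** — single-compartment conductance-based cells,
  `C_m dV/dt = −g_L(V−E_L) − Σ g̅ a^p h (V−E_rev) + I`, with first-order
  gate kinetics towards Boltzmann steady states
  `x_∞(V) = 1/(1+exp((V_half−V)/k))` at voltage-independent time constants.
  Muscles carry a fast K⁺ current (activation exponent 4, inactivating), a
  slow K⁺ current (exponent 1, non-inactivating) and an inactivating Ca²⁺
  current; neurons a fast K⁺ and an inactivating Ca²⁺ current. A linear
  calcium pool integrates the calcium current:
  `d[Ca]/dt = −ρ I_Ca − [Ca]/τ_Ca` (inward current raises `[Ca]`).
* **C1** — as C, but chemical transmission is graded:
  `s_∞ = 1/(1+exp((V_th−V_pre)/δ))`, `τ_s ds/dt = s_∞ − s`,
  `I = w s (E_syn − V_post)`. Continuous transmission is the better
  approximation for *C. elegans*, whose neurons mostly signal with graded
  potentials; the functional form follows the classic stomatogastric
  graded-synapse model, with one simplification: the presynaptic-dependent
  timescale of that model is replaced by a constant `τ_s`. Voltage-dependent
  gate time constants are deferred for the same reason — every relaxation
  is then a known exponential, which keeps each piece testable in closed
  form.

Units are fixed package-wide at mV, ms, nS, pA, pF, µM. The system is
self-consistent (nS·mV = pA, pA/pF = mV/ms), so no conversion constants
appear in the equations.

Sign conventions: all synaptic and gap-junction currents are *into* the
postsynaptic cell, depolarising positive. Excitatory reversal defaults to
0 mV and inhibitory to −70 mV, overridable per parameter set.

### Shipped constants

The parameter files under `inst/extdata/parameters/` are the single source
of every constant; nothing is hard-coded. Two choices deserve comment:

* Channel activation midpoints are placed so that every channel is
  effectively closed at the leak reversal (−60 mV). This makes the
  deterministic initial state — `V = E_L`, gates at `x_∞(E_L)`, `s = 0`,
  `[Ca] = 0` — a genuine equilibrium of the unstimulated network, which in
  turn gives simulations a reproducible, transient-free start.
* `spike_detect_threshold` is −20 mV for the conductance-based levels. The
  cells produce plateau-type depolarisations rather than overshooting
  action potentials (as *C. elegans* cells largely do), so an upward
  crossing of −20 mV with a 1 ms minimum inter-event interval is the
  operative definition of a "spike" where level C's spike-triggered
  synapses need one.
* The graded-synapse slope is `δ` = 3 mV about `V_th` = −35 mV: steep
  enough that transmission at rest (−60 mV) is negligible — preserving the
  equilibrium start — while saturating for depolarisations beyond ≈ −25 mV.

## The simulator

Integration is forward Euler at a fixed step, `dt` = 0.05 ms by default.
All per-step inputs (stimulus currents, synaptic and gap currents) are
computed from the *previous* step's state, then every cell advances — a
synchronous (Jacobi) update whose result cannot depend on cell ordering.
Spike events detected during a step act on spike-triggered synapses at the
next step. Dynamics are fully deterministic: identical network and
simulation settings give bit-identical results, which the suite asserts.

Numerical choices: gate and synapse activations are clamped to [0, 1] and
calcium to non-negative values after each Euler step (the update can
overshoot an invariant boundary by O(dt²)); a non-finite membrane potential
aborts the run naming the cell and time; the refractory period of a LIF
cell runs from the spike event (the end of the crossing step), which keeps
the simulated inter-spike interval within one step of the closed-form
value. `dt` is restricted to (0, 1] ms — beyond 1 ms the fastest gate
(τ = 2 ms) would be integrated with fewer than two steps per time constant.
Degenerate inputs are defined rather than rejected: a zero-duration
simulation returns the initial state; an empty network yields an empty
(but valid) result and export.

Forward Euler is first-order, and the suite verifies the expected
convergence: halving `dt` halves the remaining error, both for scalar gate
relaxations and for the eight-cell demonstration network. Accuracy at the
default step is checked against closed forms — passive RC charging and the
LIF inter-spike interval to 1%, gate and graded-synapse relaxations to
0.5% — rather than assumed.

## The forward-locomotion circuit

The shipped circuit instantiates the canonical forward-crawling subnetwork:
AVBL/AVBR, DB1–DB7, VB1–VB11, DD1–DD6, VD1–VD13 (39 neurons) and the four
muscle quadrants (96 cells), at level C or C1. Wiring follows class-level
hypotheses: AVB gap-couples to every B neuron; consecutive B neurons chain
through gap junctions; B-types excite and D-types inhibit their muscles; DB
excites VD and inhibits DD, VB excites DD and inhibits VD (the crossed
motif that enforces dorsoventral alternation). Every connection carries one
shared weight — the uniform-weight simplification reflecting that synaptic
strengths in the worm are unmeasured.

Design decisions where the ground truth is unavailable:

* **Innervation map.** The real neuron→muscle table is not bundled; the
  default fixture assigns each motor neuron a contiguous block of muscles
  on its own side (dorsal classes to the MD rows, ventral to the MV rows),
  consecutive blocks overlapping by one muscle, covering indices 8–24.
  Muscles 1–7 of each quadrant (the head) are driven directly by the
  stimulus protocol, and MVL24 is excluded, so exactly 95 of 96 muscles
  receive input and MVL24 stays silent. A measured table can be supplied as
  a two-column CSV (`read_innervation_csv()`).
* **Class-to-class edges.** DB→VD, DB→DD, VB→DD and VB→VD connections are
  made where the two neurons' innervated body regions overlap, not
  all-to-all: global crossed inhibition would act on the whole body at once
  and flatten the travelling wave, whereas the regional motif applies the
  crossed inhibition segment by segment.
* **CPG approximation.** The rhythm generator is not modelled; it is
  approximated by periodic current pulses into DB1 and VB1, with the
  ventral train delayed by half a period (alternating dorsal/ventral
  bends), plus a tonic current into AVB (active throughout forward
  movement) and synchronised pulses into the head muscles at the same
  period. The default period of 1250 ms gives four full waves in a 5 s
  simulation.
* **Proprioception.** Stretch-receptor feedback is approximated by a
  static, feed-forward graded excitation from each B neuron to its
  posterior neighbour (`add_proprioceptive_coupling()`); no body mechanics
  are simulated, so an actual stretch signal does not exist in the model.

None of the drive amplitudes or the uniform weight is a measured quantity.
They were calibrated once against the travelling-wave property suite
(positive head-to-tail slope in all four quadrants, oscillation at the
drive frequency, dorsal left–right synchrony, dorsoventral alternation) and
then frozen as package defaults: uniform weight 0.1 nS, proprioceptive gain
0.6 nS, CPG pulses 20 pA × 300 ms, AVB tonic 8 pA, head-muscle pulses
25 pA. The calibration's qualitative logic: the gap-junction network loads
every neuron with roughly its degree × the uniform weight, so weights much
above ~0.1 nS shunt the 0.3 nS-leak cells faster than realistic drive can
charge them; and the eleven-stage ventral B chain is the longest relay, so
it — not the seven-stage dorsal chain — sets the minimum proprioceptive
gain at which activity still propagates to the tail.

## Wave analysis

`wave_metrics()` reduces muscle calcium traces to four numbers. Peaks are
local maxima after a settling period (default analyses discard the first
CPG period), subject to a prominence threshold — at least half the
post-settle trace range above its minimum — and a 50 ms minimum separation
(earliest peak kept on ties). The head-to-tail propagation slope is the
least-squares slope of first peak time against muscle index within a
quadrant (ms per muscle; positive = towards the tail). Frequency is
1000/median inter-peak interval of the first muscle with at least two
peaks. Phase differences between paired quadrants are circular means of
per-index first-peak time differences, as a fraction of the period — the
circular mean is essential, since a difference of 0.98 periods and one of
0.02 must average near 0, not 0.5. A flat or peak-free trace raises an
error naming the muscle rather than silently degrading the fit; MVL24,
silent by construction, is therefore excluded from the default analysis
order.

## The synthetic-connectome generator

`generate_synthetic_connectome()` emulates the statistical features of the
real wiring that the package's own machinery is sensitive to: a neuron and
muscle division with muscles never presynaptic, independent directed
chemical connections at a chosen density, unordered gap-junction pairs,
contact counts from a geometric distribution shifted to minimum 1 (the
real contact-count distribution is similarly right-skewed), and a chosen
fraction of GABAergic neurons. It is seeded and reproducible, and it is
first-class, tested code — the parser/builder oracle suites run on it.

What it does *not* emulate: spatial structure (connection probability in
the worm falls with soma distance), the heavy-tailed degree distribution of
hub interneurons, class-stereotyped wiring, or left–right symmetry. Tests
passing on synthetic instances therefore establish the correctness of
parsing, subsetting, weight resolution and export on realistic table
*shapes* — not that any biological conclusion transfers to the real
connectome.

## Problem sizes and runtime

The suites are sized to what the checks need, not more: closed-form
dynamics oracles run single cells or scalar ODEs for 60–500 ms; builder and
parser oracles use 20 seeded synthetic connectomes of 25–30 cells;
the convergence study runs the eight-cell demonstration network at
`dt` = 0.05/0.025/0.0125 ms for 150 ms; and the full locomotion
demonstration simulates all 135 cells for 5 s at `dt` = 0.05 ms
(100 000 steps), sampling every 10th step.

## Known limitations

* Channel kinetics use constant time constants and Boltzmann steady
  states; kinetic-scheme/Markov channels and voltage-dependent τ are out of
  scope, as are multicompartmental morphologies.
* Plastic (activation-history-dependent) chemical synapses are not
  implemented.
* Polarity-by-transmitter ignores postsynaptic receptor identity; the
  locomotion circuit's crossed-inhibition polarities are hypotheses, not
  measurements.
* The NeuroML export is a structural subset (populations, positions,
  projections, weights, inputs) intended for interchange and visualisation;
  it does not embed the dynamics definitions, for which the built-in
  simulator is the executable semantics.
* Forward Euler favours transparency over speed; stiff additions (fast
  voltage-dependent τ, large conductances) would need smaller steps rather
  than being handled adaptively.
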