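---
title: "Screening multi-compartment interneuron models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening multi-compartment interneuron models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuroscreen)
```

# The problem

Many interneuron types have well-described morphology and firing patterns
but unknown voltage-gated channel (VGC) complements. `neuroscreen`
implements a semi-automated strategy for proposing channel types, maximal
conductance densities, and spatial distributions for such cells: generate a
Cartesian grid of candidate multi-compartment models, simulate a small set
of current-injection protocols (CIPs) on each, discard models that fail
qualitative signature features, score the survivors against reference
measurements with a normalized distance, rank them, and visualize the
conductance space by dimensional stacking so a human can refine the grid.
The automated steps (simulate, eliminate, measure, score, rank, plot) are
package functions; grid refinement and channel-type changes remain
deliberate human decisions, supported by the plots and survivor reports.

# Model structure

## Morphology and compartmentalization

Morphologies are branched trees of unbranched *sections*, each a 3D
polyline with per-point diameters, read from standard SWC
(`read_swc()`). The soma (1-3 SWC samples) is the root section, treated as
a cylinder sequence. Axonal arbors can be cut to a stub with `trim_axon()`;
the stub's passive parameters then compensate for the lost membrane area
(see below).

`compartmentalize()` splits each section into an odd number of equal-arc
compartments whose length is at most a fraction (default 0.1) of the AC
length constant at 100 Hz — the classical d-lambda rule — computed from the
section's mean diameter and the regional Ra and Cm. Compartment surface
areas use trapezoidal integration of the diameter profile, and half-axial
resistances use the frustum formula per polyline segment, so totals are
invariant (within 0.5%) under re-compartmentalization. A fixed-length
policy exists for controlled numerical experiments.

Path distance is measured from the soma section midpoint, so the soma
half-length is included in "distance from soma"; the convention is
documented rather than universal, and all internal consumers (Boltzmann
profiles, analysis tables) use it consistently.

## Passive properties

Defaults are Cm = 0.9 uF/cm2, Ra = 255 Ohm cm, Gm = 1.9e-5 S/cm2, with the
axon-stub override Cm = 4 uF/cm2, Ra = 300 Ohm cm, Gm = 1.85e-4 S/cm2 that
compensates a trimmed axonal arbor. The leak reversal defaults to the
target resting potential (-69.7 mV), which *is* the passive resting
potential by construction; with active channels open at rest the two drift
apart slightly, and `fit_eleak()` can re-center the settled somatic
potential by root finding when exactness matters.

## Channel kinetics are data

Channel models are Hodgkin-Huxley gates with sigmoid steady states
`x_inf(V) = 1/(1 + exp(-(V - vhalf)/k))` and bell-shaped time constants
`tau(V) = base + amp/(exp((V-vpeak)/kl) + exp(-(V-vpeak)/kr))`, read from a
YAML file (`inst/extdata/channels.yml`) so kinetics are editable data, not
code. The shipped library covers transient and persistent sodium (na_t,
na_p), fast and faster delayed-rectifier potassium (kdrf, kdrf_faster, the
latter Kv3-like: high activation threshold, sub-millisecond kinetics), a
slow delayed rectifier (kdrs), and an A-type potassium channel (ka).
Reversals are fixed at E_Na = 50 mV and E_K = -77 mV.

The shipped parameter values were calibrated once, by hand, so that the
fixture cell expresses the four signature response regimes that the
screening pipeline is designed to capture — hyperpolarization without sag,
passive depolarization at small steps, tonic spiking at moderate steps,
and depolarization block (initial spiking, then silence, then clean
repolarization) at strong steps — with the conductance densities in the
soma-and-proximal-dendrite regime used by the screening grids. They are a
working interneuron channel set in the standard formalism, not a
transcription of any specific published channel model; anyone with
voltage-clamp constraints for a particular cell type should replace the
YAML entries. Two properties of the calibration deserve note because they
shape screening behavior: sodium inactivation is steep (k = -3 mV), which
separates the tonic-firing regime from the depolarization-block regime and
removes a depolarized stable point that would otherwise prevent
repolarization after block; and the A-type current inactivates near -45 mV,
so it contributes a transient outward brake in exactly the voltage band
where persistent inward currents would otherwise latch the membrane.

## Spatial distributions

`scenario_channels()` encodes the distribution scenarios: S.1 and S.2 put
all channels in the soma (S.1 with kdrf + kdrs, S.2 with the faster kdrf
and no kdrs); SD distributes na_t, ka and kdrf_faster uniformly over soma
and dendrites; SDprox.1 confines them to the soma and proximal dendrites
through a Boltzmann fall-off `f(p) = G - G/(1 + exp(k (d - p)))` with
steepness k = 10/um and cutoff d of 55, 75 or 95 um; SDprox.2 additionally
restricts ka to the soma. Persistent sodium is soma-only in every scenario.

# Simulation

The integrator solves `C dV/dt = -I_ion - I_axial + I_inj` on the
compartment tree with a theta method (backward Euler by default,
Crank-Nicolson optional), one exact tree-structured elimination per step
(Hines ordering), and Rush-Larsen exponential gating updates from
voltage-indexed lookup tables (0.05 mV grid, rebuilt per dt). Units are
mV/ms/um internally, S/cm2 for densities, nA for point currents, uS for
synaptic weights; all conversions happen in one assembly routine.

Defaults: dt = 0.025 ms; a 500 ms settle-to-steady-state pre-run before
each protocol (discarded); CIP timing of 100 ms baseline, 1000 ms pulse,
200 ms recovery, chosen so the "final 700 ms" and "first 100 ms" feature
windows fit inside the pulse. Backward Euler is first-order, and in the
tonic regime successive spikes accumulate phase drift under step
refinement; convergence is therefore assessed on early spike times (first
two spikes move by < 0.2 ms when dt is halved), which is the meaningful
statement for a fixed-step method on a near-periodic orbit.

Synapses are two-state double exponentials, `G = weight x factor x
(exp(-t/tau2) - exp(-t/tau1))` with tau1 = 0.2 ms, tau2 = 2 ms, reversal
0 mV, and the factor normalizing the single-event peak to the weight.
Optional Gaussian white-noise current injection is seeded and reproducible;
it is off during screening (irregular firing is a demonstration feature,
not a screening criterion).

# Features, elimination, and the quality metric

`measure_cip()` computes a fixed measurement set per CIP class — 5 at the
hyperpolarizing step, 1 at the passive depolarization, 10 at the active
depolarization, 2 at the depolarization-block step. Membrane-potential
differences are mean-during-pulse minus mean-during-baseline; the
block-step difference uses only the final 700 ms of the pulse. Spikes are
detected as local maxima above 0 mV, thresholds at the first point where
dV/dt exceeds 20 mV/ms on the upstroke, amplitudes peak-minus-threshold,
half-widths at half-amplitude, and AHP depths threshold-minus-minimum
before the next spike; all criteria are configurable
(`feature_config()`) because toolbox definitions differ. The sag time
constant is a single-exponential fit (log-linear least squares) from the
trace minimum to pulse end, returning 0 when the rebound is below 0.1 mV.
Spike-frequency adaptation is the mean of the last two ISIs over the mean
of the first two. Spike rate is count over pulse duration; note that a
packaged experimental reference may legitimately be internally inconsistent
with any single definition (selected-trace values are used verbatim in the
metric rather than recomputed).

`eliminate_model()` applies the five failure criteria: spikes during the
passive step; fewer than three spikes, or failure to repolarize, at the
active step; and spikes in the final 700 ms, spikes in the recovery period,
or failure to repolarize at the block step. "Failure to repolarize" is
operationalized as the mean potential over the last 50 ms of the recovery
deviating more than 10 mV from baseline (the qualitative criterion needs a
tolerance; both are configurable).

The quality metric is `sum(|x_i - y_i|) / (N sigma_i)` with sigma = 1 —
a mean absolute deviation, implemented exactly as printed in the model
database literature that names it a "normalized Euclidean distance"; an
RMS variant is available behind `type = "l2"` for sensitivity checks.
Per-CIP distances are averaged so each signature feature carries equal
weight (measurements within a CIP consequently do not). Eliminated models
carry the sentinel distance 100 and rank after all survivors; remaining
ties break lexicographically on parameter values so ranking is
deterministic.

# CBDR layouts

Dimensional stacking maps the N-dimensional grid onto a 2D image:
parameters are ordered by *impact*, defined here as the range of per-level
marginal mean distances (the defining literature leaves the ordering
criterion open; this marginal-range heuristic is simple and reproducible,
with name-alphabetical tie-breaks), and assigned alternately to the y and
x axes, outermost first, with level order ascending so low-conductance
models land in the bottom-left. Eliminated pixels render black. Every
pixel maps bijectively to one model, and `plot_cbdr()` writes both the PNG
and a pixel-to-model sidecar table.

# Downstream analyses

*Electrotonic maps* solve the passive steady state directly from the
compartment conductance matrix: a 1 mV signal is applied at the upstream
point and L = ln(upstream/downstream) is reported per location, in both
directions (into the soma and out of it). The natural logarithm is the
documented choice (a base-10 variant is one argument away, since the
surrounding literature is not unanimous). L is additive along unbranched
paths and matches the cosh closed form on uniform cables within 1%.

*bAP profiles* drive the soma with three 2 ms, 800 pA pulses and report
peak-minus-baseline per dendritic compartment against path distance. The
inter-pulse spacing is not a constrained quantity; 10 ms (a 100 Hz
triplet) is used.

*Threshold-weight scans* place a single-spike synapse at successive
dendritic locations and find the minimal weight driving the soma past
-20 mV. The search brackets the threshold by doubling from 1e-4 uS and
refines by bisection in log-weight to three significant figures — the same
resolution as a fine geometric sweep at a small fraction of the
simulations (~25 per location instead of several hundred). Each trial
reuses a cached resting state, simulating only a 60 ms window. The local
depolarization in the first 1 ms after the synaptic event is recorded at
the synapse; locations where it reaches 90% of the driving-force ceiling
|V_rest - e| are flagged saturated. Locations that cannot spike at the
schedule maximum (10 uS) are reported unreachable rather than searched
indefinitely.

`gmax_from_density()` is the exact spherical-soma conversion
`G = density x 4 pi r^2` (0.25 S/cm2 over a 10 um sphere is pi uS =
3141.6 nS).

# The synthetic fixture

`make_fixture_morphology()` builds a stylized small vertically oriented
interneuron: a 15 x 15 um somatic cylinder; tree "1", long (~420 um of
path) and sparsely branched with a thin distal extension so synaptic
saturation and unreachable locations actually occur within the arbor; tree
"2", heavily branched (5 branch points) with the largest membrane area;
tree "3", small, thin and branched (3 branch points, the smallest area, so
tree comparisons of electrotonic attenuation have a clear sign); and a
30 um axonal stub. Dendritic diameters taper 3.6 to 0.5 um; lengths carry
a +/-3% seeded jitter, and the same seed reproduces byte-identical SWC.
The geometry was sized once so the passive input resistance (~630 MOhm)
places the rheobase between the +20 and +50 pA steps, which is what makes
the four signature features expressible at the standard CIP amplitudes.

Ground-truth densities sit in the soma-and-proximal-dendrite conductance
regime of the screening grids (e.g. SDprox.2: na_t 0.15, na_p 5e-5, ka
0.07, kdrf_faster 0.295 S/cm2, cutoff 75 um). Screening grids bracket each
varied conductance with factors 0.5/1/1.75 — deliberately broad, as
starting grids are — so a 27-model database contains surviving models,
models eliminated for every criterion class, and in particular models that
spike during the passive step.

What the fixture does *not* emulate: experimental variability (no
measurement noise, no cell-to-cell histograms), sag-generating HCN
currents (the hyperpolarizing response is purely passive, so sag
measurements are exercised by constructed traces instead), calcium
channels and calcium dynamics, and a real reconstruction's morphometrics.
Passing fixture tests therefore demonstrates that the pipeline recovers
known generators and orders model quality correctly under the stated
conditions, not that the shipped kinetics describe any particular cell.

# Problem sizes and runtime choices

The test suite screens the 27-model grid once (~2 minutes on one CPU) and
shares it across screening, fixture, and acceptance tests; the
cutoff-distance recovery uses a 9-model grid; threshold-weight scans in
tests restrict to the distal locations where the interesting transitions
occur. The acceptance script re-screens the 27-model grid from scratch.
Full-scale grids (243-432 models) are supported by the same functions and
are simply a larger loop; the records table and layout logic are
independent of grid size.

# Known limitations

- Backward Euler is robust but first-order; tight spike-time work should
  use the Crank-Nicolson option or a reduced dt.
- The elimination thresholds (repolarization tolerance, spike detection
  level, slope criterion) are explicit parameters with sensible defaults,
  not universal constants.
- The strategy's manual steps (grid refinement, channel-type changes) are
  intentionally not automated; `recovery_harness()` and the CBDR plots are
  the support surface for them.
- Model quality is relative to the chosen reference measurements; with
  sigma fixed at 1, measurements with large numeric ranges dominate within
  a CIP.
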