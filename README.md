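# neuroscreen

Semi-automated screening of multi-compartment conductance-based neuron
models, in R.

## The problem

For many interneuron types the morphology and firing behavior are known but
the voltage-gated channel (VGC) complement — which channels, at what
maximal conductance densities, distributed where — is not. `neuroscreen`
implements a population-of-models strategy for proposing answers: build a
Cartesian grid of candidate models over conductance densities (and,
optionally, over the spatial extent of the dendritic channel distribution),
simulate a fixed set of somatic current-injection protocols (CIPs) on every
grid member, eliminate models that fail qualitative *signature features*
(no spiking at small depolarizations, tonic spiking at moderate ones,
depolarization block at strong ones, sag-free hyperpolarization), score the
survivors against reference measurements, rank them, and render the
conductance space as a dimensional-stacking (CBDR) image for human-guided
grid refinement.

The quality metric for a model with measurements `x` against reference
measurements `y` is the sigma-scaled mean absolute deviation

    d(x, y) = sum_i |x_i - y_i| / (N * sigma_i),        sigma_i = 1,

evaluated per CIP and averaged over the four CIPs so each signature feature
carries equal weight. Eliminated models carry the sentinel distance 100 and
rank last.

The package contains, as first-class tested components:

- an SWC morphology reader/writer, axon trimming, isopotential
  compartmentalization (d-lambda rule), and tree morphometrics;
- Hodgkin–Huxley channel kinetics as a declarative YAML library, spatial
  distribution scenarios (soma-only, uniform, Boltzmann proximal fall-off
  `f(p) = G - G/(1 + exp(k (d - p)))`), and model assembly;
- an implicit branched-cable integrator (backward Euler / Crank–Nicolson,
  Hines tree solve, Rcpp) with current-clamp protocols, double-exponential
  synapses, and seeded white-noise injection;
- electrophysiological feature extraction (spike shape, sag, depolarization
  heights, depolarization block) and criterion-based elimination;
- database generation, ranking, and CBDR layouts/plots;
- downstream analyses: passive electrotonic attenuation maps,
  backpropagating-spike amplitude profiles, synaptic threshold-weight
  scans, and density-to-point-conductance conversion;
- a deterministic synthetic-fixture module (stylized interneuron
  morphologies and ground-truth references) so the whole strategy is
  testable without any external reconstruction.

## Worked example

Screen a 27-model grid around a known generating model on the synthetic
fixture cell:

```r
library(neuroscreen)

morph  <- make_fixture_morphology(fixture_morph_spec(seed = 1))
cmodel <- compartmentalize(morph)
tree_stats(morph)
#   tree_label n_branch_points surface_area_um2 max_distal_length_um summed_length_um
#            1               2           3230.6                434.2            583.3
#            2               5           2170.8                180.7            479.5
#            3               3           1023.4                125.7            284.6
#         axon               0            135.7                 30.0             30.0

truth     <- ground_truth("SDprox.2")     # na_t, na_p, ka, kdrf_faster + cutoff d
reference <- make_reference(truth, cmodel)
round(reference$active_depol, 3)
#        active_vm_diff   interspike_interval      first_spike_time
#                24.987                13.678                46.750
#  spike_threshold_mean  spike_halfwidth_mean  spike_amplitude_mean
#               -36.495                 0.230                56.625
#            spike_rate        spike_ahp_mean              n_spikes
#                70.000                14.682                70.000
# spike_freq_adaptation
#                 0.774

db <- generate_database(cmodel, "SDprox.2", fixture_grid("SDprox.2"), reference)
db
# Model database (scenario SDprox.2): 27 models, 2 survivors
#   best distance: 0
head(db$records[order(db$records$rank),
                c("na_t", "ka", "kdrf_faster", "eliminated", "distance", "rank")], 5)
#  na_t    ka kdrf_faster eliminated distance rank
# 0.150 0.070      0.2950      FALSE     0.00    1
# 0.150 0.070      0.1475      FALSE     1.22    2
# 0.075 0.035      0.1475       TRUE   100.00    3
# 0.075 0.035      0.2950       TRUE   100.00    4
# 0.075 0.035      0.5162       TRUE   100.00    5
```

The generating densities are recovered at rank 1 with distance 0; models
that fail a signature feature (for example, spiking during the +20 pA
passive step) are eliminated and carry the sentinel distance 100. A CBDR
image of the parameter space:

```r
plot_cbdr(cbdr_layout(db), "cbdr.png")   # + pixel-to-model sidecar table
```

And the spherical-soma conductance conversion used when comparing densities
with dynamic-clamp point conductances:

```r
gmax_from_density(0.25, 10)   # 0.25 S/cm2 over a 10 um radius sphere
# [1] 3141.593                # ~ pi uS = 3142 nS
```

A thin command-line front end over the same functions lives in
`inst/scripts/neuroscreen-cli.R` (subcommands `fixtures`, `simulate`,
`screen`, `analyze`). The methods vignette
(`vignettes/screening-methods.Rmd`) documents the model, the measurement
definitions, the numerical choices, and the fixture's scope.

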