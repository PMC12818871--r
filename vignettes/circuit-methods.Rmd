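---
title: "Methods: surrogate circuit physiology, calibration and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate circuit physiology, calibration and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`cortexsim` implements, at desk scale, the physiology-side methods used to
bring large biophysically detailed cortical models into an in vivo-like
regime and to run in silico experiments on them: compensation of missing
extrinsic input by Ornstein-Uhlenbeck (OU) somatic conductance injection
with an iterative population-wise firing-rate calibration; stochastic
multivesicular short-term-plasticity synapses; thalamic stimulus
pipelines; optogenetic and lesion perturbations; evoked-response
validation metrics; contrast-tuning and modulation models; mutual
information analysis of rate and synchrony codes; and structure-function
analysis with directed simplices and meso-scale connectivity graphs.

All network-level algorithms are exercised on a **seeded surrogate
network**: nine layer-wise excitatory and inhibitory populations (L1_I,
L23_E ... L6_I) of leaky integrate-and-fire (LIF) point neurons with
conductance-based synapses, 200 neurons per population by default. The
substitution of point neurons for morphologically detailed
multicompartment models is deliberate: every algorithm in the package
interacts with neurons only through rates, spikes, conductances and
somatic injections, so nothing downstream depends on morphology. What the
surrogate does *not* emulate — dendritic integration, morphology-specific
synapse placement, cell-type diversity beyond the E/I split per layer —
limits what passing tests show about real tissue: they validate the
*methods* (the calibration loop converges, the estimators are unbiased,
the perturbation arithmetic is exact), not the biological realism of any
particular simulated trace.

## Neuron and synapse model

Neurons follow the conductance-based LIF equation integrated with
fixed-step exponential Euler at `dt = 0.1` ms (the sub-millisecond
resolution also used for stimulus evaluation). Per-population leak
conductances vary between 4.5 and 7 nS, giving heterogeneous input
conductances `G_in` across populations; inhibitory cells have smaller
capacitance (faster membranes), a slightly lower threshold and shorter
refractoriness, making them more excitable, consistent with the higher
inhibitory rates observed in vivo.

Synapses implement the stochastic Tsodyks-Markram model extended to
multivesicular release. Each connection (one edge, aggregating `nsyn`
anatomical contacts) carries a pool of `NRRP * nsyn` release-ready
vesicles. At a presynaptic spike the utilisation variable is facilitated
(`u <- u * exp(-dt/F) + U_eff * (1 - u * exp(-dt/F))`), each available
vesicle releases independently with probability `u`, and released
vesicles recover independently with time constant `D`. `U_eff` is the
calcium-scaled release probability: a Hill function of extracellular
calcium with the pathway's Hill coefficient, normalised to equal `U_SE`
at the 2.0 mM in vitro reference. The half-saturation constant is not a
published quantity; it is a configuration parameter with default 2.5 mM,
which places the in vivo range (1.0-1.1 mM) on the steep, strongly
sub-linear part of the curve. Each released vesicle contributes a
peak-normalised bi-exponential conductance transient of amplitude `ghat`
(the alternative convention, `ghat/NRRP` per vesicle, is available via
`quantal_pool = TRUE`). Excitatory synapses add an NMDA component
weighted by `ghat_ratio` and a sigmoidal Jahr-Stevens magnesium-block
factor (Mg and its kinetics are configuration constants: 1 mM, rise 0.29
ms, decay 43 ms). A slow GABA_B component is deliberately absent: it is
specific to neurogliaform synapses, which the surrogate's four
class-level pathways (E->E, E->I, I->E, I->I) do not distinguish.
Spontaneous single-vesicle releases occur as independent Poisson events
per synapse; by default they deplete the pool (single-vesicle
utilisation), switchable via `spont_depletes`.

Default pathway strengths (E->E 0.6 nS, E->I 0.7 nS, I->E 1.1 nS, I->I
0.9 nS, with depressing E2-like dynamics for excitatory and fast GABA_A
for inhibitory pathways) give single-connection PSPs of a few tenths of
a millivolt at the in vitro calcium reference. They place the connected
surrogate in the reported recurrence regime — connected rates exceed
unconnected rates by tens of percent, more so for excitatory
populations — so the connected/unconnected mapping of the calibration
loop is genuinely nonlinear while the loop remains well conditioned and
activity stays stable (non-bursting) across the explored meta-parameter
ranges. Stronger coupling is possible but puts the network near its
recurrent instability, where a fraction of a percent of injection
changes rates by tens of percent and no smooth rate mapping can be
inverted reliably at desk scale.

# Missing-input compensation and calibration

Missing extrinsic synapses are compensated by an excitatory OU
conductance injected at the soma, one statistically independent stream
per neuron, parameterised as percentages `OU_mu`, `OU_sigma` of the
cell's input conductance at rest, with `OU_sigma = R_OU * OU_mu` tied by
the noisiness meta-parameter. The discretisation is exact
(`g(t+dt) = g0 + (g(t)-g0) e^(-dt/tau) + sigma sqrt(1-e^(-2dt/tau)) N(0,1)`),
and negative excursions are clipped at zero only at the point of
injection, so the pre-clipping trace retains the stationary OU moments
the tests assert. The correlation time `tau = 3` ms and the excitatory
reversal (0 mV) are configuration defaults from the point-conductance
background-input convention; neither is prescribed elsewhere.

The calibration algorithm finds, for ten target levels
`P_FR in (0, 1]`, the per-population `OU_mu` producing connected rates
`C_FR = P_FR * V_FR`:

1. **chi mapping** (`learn_chi`): 1-second simulations of the
   *disconnected* network along the line `OU_sigma = R_OU * OU_mu` give
   a monotone interpolation table from injection to unconnected rate
   per population. With no synapses active it is independent of
   calcium. The default grid spans 0-50% in 5% steps; if targets are
   unreachable the caller widens the grid upwards.
2. **phi mapping** (`fit_phi`): the map from unconnected to connected
   rates is approximated per population by
   `C_FR = alpha * exp(beta * U_FR) + kappa`. The least-squares fit is
   weighted by `1/C_FR^2`: convergence is judged on the *relative*
   (P_FR-normalised) scale, and without the weighting the highest-rate
   samples dominate the loss and bias the low-rate end of the mapping,
   which is exactly where the smallest target levels live. Collinear
   samples fall back to a flagged linear fit.
3. **Iteration** (`calibrate_compensation`): starting from the identity
   mapping (cold start, levels up to `P_max = 0.5`; later iterations use
   `P_max = 1`), each iteration simulates the connected network for
   6.5 s per level at `U_FR = phi^{-1}(P_FR * V_FR)`, discards a 500 ms
   settling window, measures `C_FR`, refits phi to the newest samples
   and re-inverts. Several numerical safeguards surround the
   refit-invert core, needed because near the target states the
   surrogate's recurrent gain is appreciable and rate measurements on
   200-neuron populations are noisy: (i) phi inversion is capped at one
   sampled-range-width above the largest `U_FR` the fit has seen (the
   exponential extrapolates explosively), and a level whose `P_FR`
   exceeds anything simulated so far is additionally capped at
   ray-proportional growth from the level below it; (ii) the update
   from one iteration to the next is relaxed (`damping = 0.7`);
   (iii) once a level has been visited, each population's guess is
   refined by a local exponential inversion — the slope of log connected
   rate in `U_FR`, regressed over the level's recent visits when they
   span enough `U_FR` and taken from the global fit's derivative
   otherwise — with graduated step clamps and a dead zone at the
   sampling-noise floor; in warm starts the coherent (across-population)
   component of the correction is applied at half gain, because
   correcting it in every population simultaneously overshoots through
   recurrent coupling; and (iv) at levels with `P_FR >= 0.75` rates are
   averaged over two independent simulations — the network-wide
   fluctuations of the strongly recurrent high-activity states are
   coherent across populations, so they do not average out over neurons
   and replicate runs are the desk-scale analogue of the far larger
   populations the measurement was designed for. A level
   terminates when the Euclidean distance across the nine populations
   between observed and target `P_FR` values falls below `tol = 0.1`
   (the tolerance is not a published value; it is exposed in the
   interface). Simulations showing network-wide bursting — binned
   network spike counts with a Fano factor above 10 and a mostly-silent
   profile between peaks — are excluded from the phi fit and flagged;
   the Fano criterion is rate-independent, so sparse asynchronous
   activity at low levels is not misclassified. Warm starts reuse both
   the phi mapping and the per-level unconnected-rate targets
   (`U_levels`) calibrated for a neighbouring meta-parameter
   combination, so the first warm iteration simulates directly at the
   previous solution and later iterations only refine it. Calcium
   neighbours transfer best (chi is reused unchanged and the solution
   shifts by the release-probability scaling only; two iterations in
   the tests); transfers across `R_OU` start further away because the
   input's noise structure reshapes the unconnected-to-connected
   relation, and take four to six iterations on the surrogate.

**Desk-scale choices.** The reference vector `V_FR` preserves the
in vivo structure (I faster than E, sparse superficial E, active deep I)
but sits in the upper part of the extracellularly reported rate range
(1.2-9.6 Hz). The reason is statistical: the termination metric compares
rates *relative* to `V_FR`, and with 200-neuron populations over 6
seconds a 0.1 Hz target cannot be estimated to within 10% (the original
workflow measures rates over populations two to three orders of
magnitude larger). The settling discard (500 ms), the bursting-detector
thresholds, and the chi grid policy are likewise desk-scale artifact
decisions, stated here because no published value exists for them.

## Pathway-level calibration

`calibrate_synapse_psp` reproduces the paired-recording loop: 50 pairs,
35 repetitions each, postsynaptic cells resting at -70 mV, at 2.0 mM
calcium. The peak conductance scales the mean PSP amplitude and the
integer vesicle pool adjusts its CV (binomial release gives
`CV ~ 1/sqrt(pool)`), iterating until both match the reference within
5% and 10% or the pool reaches the univesicular lower bound, which is
flagged and returned as the boundary solution. The aggregation order for
the CV (across repetitions per pair, then averaged over pairs) is
ambiguous in the source experiments; both orders are implemented
(`aggregate` switch) and the pairs-first order is the default.
Repetitions are spaced 1 s apart by default; the residual ~5% synaptic
depression this leaves is absorbed by the calibration loop itself.

`calibrate_mpsc` maps a per-synapse spontaneous release rate to the
somatic miniature-event frequency: superposed Poisson releases, with
events merging within a 1 ms detector window (coincidence loss), fitted
with `freq = a * log(rate) + b` and inverted at the in vitro reference
frequency. Targets outside the fitted range are flagged as
extrapolation.

# Stimulus pipeline

Sensory input follows the three-step composition: a stimulus field
`rho(x, y, t)` evaluated at each fiber's flat location, an optional
kinetic transfer function, and a stochastic spiking process, so that the
fiber's train is `psi(upsilon(rho))`.

* **PSTH replay** draws, per trial, one spike time per selected fiber
  from the reference PSTH treated as a density (the figure-level
  description of the paradigm); an inhomogeneous-Poisson alternative is
  available behind the `mode` flag. The fraction `F_P` of fibers is
  selected once per experiment, not per trial.
* **Whisker-hold transfers**: position (`r_max * rho`), velocity and
  acceleration (first and second finite differences), direction
  (positively rectified first difference), with `r_max = 150` Hz and
  assignment fractions 11/58/11/20%.
* **Drifting gratings**: Michelson-contrast luminances centred on 0.5
  map linearly to rates with anchors `R(0.5) = R_bk` and
  `R(1.0) = R_peak` (defaults 0.2 and 10 Hz with `F_P = 1`, the
  calibrated combination), evaluated as a truncated sinusoid in time and
  linear fiber position (2 Hz, 0.001 cycles/um). The printed contrast
  definition has min and max transposed, which would make contrast
  negative; the implementation uses the absolute form and records the
  presumed sign typo.
* **Adapting Markov process**: the per-step hazard is the requested rate
  minus an adaptation state that increments at each emitted spike
  (default 3 Hz) and decays with `tau_adapt = 100` ms, times a
  mean-field gain `1/(1 - incr * tau_adapt / 1000)` chosen in closed
  form so the long-run emitted rate matches a constant input. The exact
  formulation of the original adapting process is not reproduced in the
  source; this subtractive form with rate-matching normalisation is an
  artifact decision, and the rate-matching contract (within 5%) is
  asserted by test.
* **Binary codes**: a two-state signal with uniform 2-7 s dwell times is
  encoded either by state-dependent Poisson rates (30/10 Hz defaults) or
  by synchrony (a shared master train during up states, independent
  trains otherwise, 20/20 Hz), reflecting that at the original in vitro
  rates a synchronous pattern would fall in a 50 ms analysis bin too
  rarely (probability 0.0135 in 5 ms windows at 2.7 Hz).

# Perturbations

Optogenetic stimulation injects somatic current proportional to each
cell's rheobase (found by bisection on 500 ms steps), scaled by relative
light intensity under the modified Beer-Lambert law
`I(d) = I0 exp(-sqrt(3 mu_a (mu_a + mu_s')) d)`. Only the two published
coefficient pairs (595 nm and 470 nm) ship as built-ins. Cells are
grouped into depth bins spanning equal intensity increments (so bins
widen with depth); each cell uses its bin-centre intensity, cells on an
edge join the shallower bin, and pulses end in a 100 ms linear ramp to
avoid rebound spikes. Lesions remove all and only the connections from
one neuron set to another, with exact set semantics.

# Analysis

PSTHs use 5 ms bins with 1-sigma Gaussian smoothing for spontaneous and
evoked histograms (1 ms / 20 bins for tuning PSTHs), optional
baseline-max normalisation, and trial averaging around stimulus onsets.
Latency is the first post-onset crossing of baseline + 5% of
(peak - baseline) — the PSTH analogue of the 5%-of-peak EPSP latency
convention, adopted because no operational PSTH latency is published —
and decay points are first post-peak crossings of the 50% and 25%
levels. The criteria check applies lag tolerances of 10/10/40 ms and the
no-secondary-rise rule (nothing more than 35% above baseline after 75
ms), with L1_I excluded. The baseline window for the evoked ratio `R_E`
defaults to the 200 ms (configurable) pre-stimulus span of the PSTH
window.

Mutual information between a cell's binned spike counts (capped, default
at 5) and the binary signal uses the plug-in estimator (Miller-Madow
correction behind a flag); significance compares against circular
time-shifts of the signal, which preserve its dwell-time structure where
a plain permutation would not. Cells that never spike are excluded.

Topology: directed simplices are counted by ordered-clique extension
over sorted adjacency intersections (each valid feed-forward ordering
enumerated exactly once), checked against an independent brute-force
subset-and-permutation oracle in the tests. The participation-weighted
mean uses the plain weighted-average convention; the variant with an
extra `1/N` prefactor that appears in print contradicts the verbal
definition of a weighted average and is available behind the `per_node`
compatibility flag. The top-5% participation set includes ties at the
cutoff. Meso-scale graphs count synapses between hexagonal flat-space
subvolumes (exact cube-rounded assignment; the flat-to-flat diameter
equals the centre pitch) and correlate pooled 5 ms binned spike counts;
within-subvolume entries use the separate E and I series. Rich-club
membership thresholds the synapse-count matrix and takes undirected
connected components (whether the original analysis used directed or
undirected components is not stated; undirected is the default and the
choice is localised in one function).

# Numerical choices and reproducibility

Every stochastic element is seeded: network construction, simulation
(one RNG stream drives OU innovations, vesicle recovery/release and
spontaneous events in a fixed traversal order), stimulus generation and
shuffle controls. Identical seeds give bit-identical spike tables. The
integrator guards against divergence (any non-finite state aborts with a
diagnostic) and the membrane update uses a series expansion of the
exponential for the very small per-step exponents, accurate to ~1e-9
relative. OU innovations use a ziggurat normal generator; release and
recovery draws use small-n Bernoulli sums, so the simulator does not
depend on library-specific distribution algorithms.

Problem sizes used by the test-suite and reproduction script: the full
surrogate (9 x 200 neurons, ~160k connections) for the calibration
convergence runs (11 one-second chi simulations and up to 8 iterations
of 10 six-and-a-half-second simulations per meta-parameter combination);
a reduced 9 x 40 fixture for the calibration property tests (parameter
recovery, contraction); 25-30 pairs with 12-15 repetitions for the PSP
protocol tests; graphs of up to 12 nodes for the simplex oracle; and
1e4-1e5 draws for the distributional oracles. These sizes were chosen so
the complete suite exercises every loop end-to-end in tens of minutes on
a single core while keeping Monte-Carlo assertions at 3-sigma margins.

# Known limitations

* The surrogate's four class-level pathways cannot express pathway
  diversity (facilitating E1 connections, neurogliaform GABA_B, VIP-like
  disinhibition); the synapse model supports them, the default network
  does not instantiate them.
* The compensation is somatic and uncorrelated by construction;
  dendritically distributed or correlated compensation is out of scope.
* Point neurons have no depth extent beyond their assigned soma depth,
  so optogenetic depth binning acts on soma depth only.
* The calibration termination metric inherits sampling noise from
  finite populations; at desk scale this sets a floor of a few
  hundredths in normalised P_FR units, which is why sub-Hz reference
  vectors are not usable with 200-neuron populations (see above).
* The mutual-information estimator is the plug-in estimator on capped
  counts; for very short recordings its bias is non-negligible and the
  Miller-Madow flag only partially corrects it. The shuffle control is
  calibrated (false-positive rate within 2 points of alpha) for the
  regimes the tests cover.
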