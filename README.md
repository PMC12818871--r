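# cortexsim

Desk-scale simulation and analysis of cortical microcircuit physiology.

Large biophysically detailed cortical models only produce in vivo-like
activity once the input from unmodeled brain regions is compensated and the
compensation is calibrated population by population. `cortexsim`
implements that workflow — and the in silico experimentation and analysis
methods built on top of it — on a seeded surrogate network of layered
leaky integrate-and-fire populations, so the algorithms can be developed,
tested and taught on a laptop:

* **Surrogate circuit** — nine layer-wise E/I populations of
  conductance-based LIF neurons connected by stochastic multivesicular
  Tsodyks–Markram synapses (release probability `U_SE` scaled by
  extracellular calcium through a Hill relation; vesicle pool `N_RRP`
  with per-vesicle recovery `D`, facilitation `F`, bi-exponential
  conductances, NMDA with Mg²⁺ block). Bit-reproducible given a seed;
  the integration core is compiled (Rcpp).
* **Missing-input compensation** — per-neuron Ornstein–Uhlenbeck
  conductance injection, `dg/dt = -(g - g₀)/τ + √D χ(t)` with
  `D = 2σ²/τ`, parameterised as percentages `OU_μ`, `OU_σ` of each
  cell's input conductance `G_in = 1/R_in` and tied by `OU_σ = R_OU·OU_μ`.
* **Calibration** — the iterative algorithm that maps injection to
  unconnected rates (χ, from short disconnected simulations) and
  unconnected to connected rates (φ, an exponential
  `C_FR = α·e^{β·U_FR} + κ` refit each iteration), targeting connected
  rates `P_FR · V_FR` for ten activity levels, with bursting exclusion
  and warm starts; plus pathway PSP mean/CV calibration of `(ĝ, N_RRP)`
  and mPSC spontaneous-rate calibration.
* **Stimuli** — PSTH replay for whisker deflections, whisker-hold kinetic
  transfer functions (position/velocity/acceleration/direction,
  `r_max = 150` Hz), drifting-grating rate fields (Michelson contrast,
  2 Hz, 0.001 cycles/µm), an adapting Markov spiking process, and binary
  rate/synchrony codes.
* **Perturbations** — optogenetic somatic injection scaled by rheobase
  and modified Beer–Lambert depth attenuation
  `I(d) = I₀·e^{-√(3μₐ(μₐ+μₛ'))·d}`, with intensity-equal depth bins and
  off-ramps; exact pathway lesions.
* **Analysis** — PSTHs with latency/decay criteria and evoked ratio
  `R_E`, connected/unconnected ratios `R_C/U`, E–I correlations, rate
  spectra, lognormal rate statistics, subthreshold-cell selection,
  mutual information with a circular-shift shuffle control,
  contrast-tuning sigmoids `R(c) = R_max·cⁿ/(cⁿ+c₅₀ⁿ)+m`,
  divisive/subtractive/saturation-additive modulation models and the
  two-stage conductance-based PC model, directed-simplex node
  participation, hypergeometric enrichment, hexagonal meso-graphs and
  rich-club detection.

## Worked example

Build the surrogate, learn the χ mapping, calibrate the compensation for
one meta-parameter combination, and inspect the result:

```r
library(cortexsim)

con <- build_surrogate(default_populations(200), seed = 7)
con
#> <connectome> 1800 neurons in 9 populations, 161825 edges (485310 synapses)

chi <- learn_chi(con, R_OU = 0.4, grid = seq(0, 50, by = 5),
                 sim_config = simulation_config(duration = 1000, seed = 1))
cal <- calibrate_compensation(con, meta_params(1.05, 0.4),
                              reference_rates(), chi, seed = 11)
cal
#> <compensation_calibration> 10 levels, 4 iterations, converged
#> final per-level distances: 0.03 0.066 0.018 0.05 0.028 0.088 0.053
#>   0.061 0.078 0.08

round(vapply(cal$tables[["P_FR=0.30"]]$params,
             function(p) p$OU_mu, numeric(1)), 1)
#>  L1_I L23_E L23_I  L4_E  L4_I  L5_E  L5_I  L6_E  L6_I
#>  23.9  23.4  22.4  25.4  22.9  28.4  24.2  24.2  23.0
```

Each level's table holds the per-population injection means (percent of
`G_in`) that make the connected network fire at `P_FR` times the
reference rates; the distances are the per-level Euclidean errors across
populations in normalised `P_FR` units (termination at 0.1). The
calibrated tables plug straight back into `simulate_network()` via
`scale_to_cell()`, and warm-start a neighbouring combination through
`phi_init = cal$phi`.

(These numbers are the printed output of running the code above; the same
run also warm-starts the neighbouring calcium level, which converges in
two further iterations.)

## Command line

A thin CLI over the package functions is installed at
`inst/cli/cortexsim` (subcommands `simulate`, `calibrate`, `analyze`),
reading/writing the package's TSV and YAML interchange formats.

See the methods vignette (`vignettes/circuit-methods.Rmd`) for the model
equations, parameter defaults and the reasoning behind every numerical
choice.
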