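#' Point-neuron parameters
#'
#' Parameters of a leaky integrate-and-fire neuron with conductance-based
#' synapses. The surrogate network substitutes these point neurons for
#' morphologically detailed multicompartment models; all calibration and
#' analysis algorithms in the package interact with neurons only through
#' rates, spikes and conductances, so they are agnostic to this choice.
#'
#' @param membrane_capacitance Membrane capacitance (pF).
#' @param leak_conductance Leak conductance (nS); must be positive.
#' @param leak_reversal Leak (resting) reversal potential (mV).
#' @param spike_threshold Spike threshold (mV).
#' @param reset_potential Post-spike reset potential (mV); must be below
#'   threshold.
#' @param refractory Absolute refractory period (ms).
#' @param excitatory_reversal Reversal potential of excitatory synapses (mV).
#' @param inhibitory_reversal Reversal potential of inhibitory synapses (mV).
#' @param threshold_sd Across-neuron standard deviation of the spike
#'   threshold (mV) within a population sharing these parameters. Real
#'   populations are heterogeneous in excitability, which smooths the
#'   population rate-vs-input curve; a population of identical thresholds
#'   would instead switch on abruptly.
#'
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(membrane_capacitance = 150,
                          leak_conductance = 6,
                          leak_reversal = -70,
                          spike_threshold = -50,
                          reset_potential = -65,
                          refractory = 2.5,
                          excitatory_reversal = 0,
                          inhibitory_reversal = -80,
                          threshold_sd = 2) {
  stopifnot(leak_conductance > 0, membrane_capacitance > 0,
            reset_potential < spike_threshold, refractory >= 0,
            threshold_sd >= 0)
  structure(list(membrane_capacitance = membrane_capacitance,
                 leak_conductance = leak_conductance,
                 leak_reversal = leak_reversal,
                 spike_threshold = spike_threshold,
                 reset_potential = reset_potential,
                 refractory = refractory,
                 excitatory_reversal = excitatory_reversal,
                 inhibitory_reversal = inhibitory_reversal,
                 threshold_sd = threshold_sd),
            class = "neuron_params")
}

#' Population specification
#'
#' @param name Population label, one of [population_names()].
#' @param count Number of neurons (> 0).
#' @param depth_range Depth interval (micrometres, surface-positive
#'   downwards) occupied by the population's somata, as a length-2 numeric.
#' @param neuron_params A [neuron_params()] object shared by the population.
#' @param subpopulation Inhibitory marker subpopulation (`"PV"`, `"Sst"`,
#'   `"5HT3aR"`) or `"none"` for excitatory populations.
#'
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, count, depth_range,
                            neuron_params = cortexsim::neuron_params(),
                            subpopulation = "none") {
  name <- match.arg(name, .pop_names)
  stopifnot(count > 0, length(depth_range) == 2, depth_range[1] < depth_range[2])
  synapse_class <- if (grepl("_E$", name)) "E" else "I"
  if (synapse_class == "E" && subpopulation != "none")
    stop("subpopulation markers apply to inhibitory populations only")
  structure(list(name = name, count = as.integer(count),
                 synapse_class = synapse_class,
                 subpopulation = subpopulation,
                 depth_range = as.numeric(depth_range),
                 neuron_params = neuron_params),
            class = "population_spec")
}

#' Default nine-population surrogate layout
#'
#' Builds the nine layer-wise E/I populations used by the seeded surrogate
#' network: layer depth ranges follow typical rat somatosensory cortex
#' proportions over a 2000 um cortical depth, and inhibitory populations are
#' tagged with the predominant marker of their layer's largest interneuron
#' class. Inhibitory neurons are given a slightly faster membrane (smaller
#' capacitance) than excitatory ones.
#'
#' @param n_per_pop Neurons per population (default 200, the surrogate used
#'   throughout the calibration examples).
#' @return A list of nine [population_spec()] objects.
#' @export
default_populations <- function(n_per_pop = 200) {
  depths <- list(L1 = c(0, 165), L23 = c(165, 665), L4 = c(665, 1115),
                 L5 = c(1115, 1530), L6 = c(1530, 2000))
  sub <- c(L1_I = "5HT3aR", L23_I = "PV", L4_I = "PV", L5_I = "Sst", L6_I = "PV")
  gl <- c(L1_I = 4.5, L23_E = 7, L23_I = 5, L4_E = 6, L4_I = 5.5,
          L5_E = 5, L5_I = 6, L6_E = 6.5, L6_I = 5.5)
  pops <- lapply(.pop_names, function(nm) {
    layer <- sub("_.*", "", nm)
    is_e <- grepl("_E$", nm)
    np <- neuron_params(
      membrane_capacitance = if (is_e) 150 else 100,
      leak_conductance = unname(gl[nm]),
      spike_threshold = if (is_e) -50 else -51.5,
      refractory = if (is_e) 2.5 else 1.5)
    population_spec(nm, n_per_pop, depths[[layer]], np,
                    subpopulation = if (is_e) "none" else unname(sub[nm]))
  })
  names(pops) <- .pop_names
  pops
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s (%s%s): %d neurons, depth %g-%g um\n",
              x$name, x$synapse_class,
              if (x$subpopulation != "none") paste0("/", x$subpopulation) else "",
              x$count, x$depth_range[1], x$depth_range[2]))
  invisible(x)
}
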