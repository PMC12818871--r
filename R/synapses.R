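#' Stochastic multivesicular Tsodyks-Markram synapse parameters
#'
#' Parameters of the short-term-plasticity synapse model used throughout the
#' surrogate network. A presynaptic action potential utilises a pool of
#' `vesicle_pool_NRRP` release-ready vesicles: each available vesicle
#' releases independently with the current utilisation probability, release
#' probability is scaled by extracellular calcium through a Hill relation,
#' released vesicles recover independently with time constant
#' `depression_D`, and utilisation facilitates at each spike and relaxes
#' back with time constant `facilitation_F`. Each released vesicle
#' contributes a bi-exponential postsynaptic conductance transient.
#'
#' @param peak_conductance_ghat Peak conductance per released vesicle (nS)
#'   under the default quantal convention (see `quantal_pool`).
#' @param release_prob_USE Utilisation of synaptic efficacy (release
#'   probability at the 2.0 mM in-vitro calcium reference), in (0, 1].
#' @param depression_D Vesicle recovery time constant (ms).
#' @param facilitation_F Facilitation time constant (ms).
#' @param decay_tau Decay time constant of the postsynaptic conductance (ms).
#' @param rise_tau Rise time constant of the postsynaptic conductance (ms).
#' @param vesicle_pool_NRRP Number of release-ready vesicles per synaptic
#'   contact (integer >= 1).
#' @param hill_coefficient_UHill Hill coefficient of the calcium scaling of
#'   release probability; 0 disables calcium scaling.
#' @param conductance_ratio_ghat_ratio NMDA/AMPA peak-conductance ratio for
#'   excitatory synapses (GABA_B/GABA_A would take this slot for inhibitory
#'   synapses; the surrogate keeps the slow inhibitory component off).
#' @param spontaneous_rate Rate of spontaneous single-vesicle releases per
#'   synaptic contact (Hz).
#' @param inhibitory Logical; `TRUE` for GABAergic pathways.
#' @param quantal_pool Logical; if `TRUE`, `peak_conductance_ghat` is the
#'   peak conductance of the whole pool and each vesicle contributes
#'   `ghat / NRRP` (the alternative quantal convention).
#'
#' @return An object of class `tm_synapse_params`.
#' @export
tm_synapse_params <- function(peak_conductance_ghat = 0.35,
                              release_prob_USE = 0.5,
                              depression_D = 650,
                              facilitation_F = 20,
                              decay_tau = 1.7,
                              rise_tau = 0.2,
                              vesicle_pool_NRRP = 2,
                              hill_coefficient_UHill = 2.8,
                              conductance_ratio_ghat_ratio = 0,
                              spontaneous_rate = 0.01,
                              inhibitory = FALSE,
                              quantal_pool = FALSE) {
  stopifnot(peak_conductance_ghat >= 0,
            release_prob_USE > 0, release_prob_USE <= 1,
            depression_D > 0, facilitation_F >= 0, decay_tau > 0,
            rise_tau >= 0, rise_tau < decay_tau,
            vesicle_pool_NRRP >= 1,
            vesicle_pool_NRRP == round(vesicle_pool_NRRP),
            hill_coefficient_UHill >= 0, spontaneous_rate >= 0)
  structure(list(peak_conductance_ghat = peak_conductance_ghat,
                 release_prob_USE = release_prob_USE,
                 depression_D = depression_D,
                 facilitation_F = facilitation_F,
                 decay_tau = decay_tau,
                 rise_tau = rise_tau,
                 vesicle_pool_NRRP = as.integer(vesicle_pool_NRRP),
                 hill_coefficient_UHill = hill_coefficient_UHill,
                 conductance_ratio_ghat_ratio = conductance_ratio_ghat_ratio,
                 spontaneous_rate = spontaneous_rate,
                 inhibitory = inhibitory,
                 quantal_pool = quantal_pool),
            class = "tm_synapse_params")
}

#' Default pathway parameters for the surrogate network
#'
#' Four synapse-class pathways (E->E, E->I, I->E, I->I). Excitatory
#' pathways are depressing (E2-like: moderate release probability, slow
#' vesicle recovery, brief facilitation) and carry an NMDA component;
#' inhibitory pathways are fast GABA_A conductances. Peak conductances are
#' set so that single-connection somatic PSPs are a few tenths of a
#' millivolt, in the range reported for cortical paired recordings.
#'
#' @return Named list of [tm_synapse_params()], keyed by pathway label.
#' @export
default_pathway_params <- function() {
  list(
    `E->E` = tm_synapse_params(peak_conductance_ghat = 0.6,
                               release_prob_USE = 0.5, depression_D = 650,
                               facilitation_F = 20, decay_tau = 1.7,
                               vesicle_pool_NRRP = 2,
                               conductance_ratio_ghat_ratio = 0.8),
    `E->I` = tm_synapse_params(peak_conductance_ghat = 0.7,
                               release_prob_USE = 0.5, depression_D = 650,
                               facilitation_F = 20, decay_tau = 1.7,
                               vesicle_pool_NRRP = 2,
                               conductance_ratio_ghat_ratio = 0.4),
    `I->E` = tm_synapse_params(peak_conductance_ghat = 1.1,
                               release_prob_USE = 0.25, depression_D = 700,
                               facilitation_F = 20, decay_tau = 8,
                               vesicle_pool_NRRP = 1, inhibitory = TRUE),
    `I->I` = tm_synapse_params(peak_conductance_ghat = 0.9,
                               release_prob_USE = 0.25, depression_D = 700,
                               facilitation_F = 20, decay_tau = 8,
                               vesicle_pool_NRRP = 1, inhibitory = TRUE))
}

#' Initialise the state of one Tsodyks-Markram connection
#'
#' @param params A [tm_synapse_params()] object.
#' @param n_contacts Number of synaptic contacts aggregated into the
#'   connection; the vesicle pool is `NRRP * n_contacts`.
#' @return A list with elements `available`, `u`, `t_last` and `pool`.
#' @export
tm_init_state <- function(params, n_contacts = 1) {
  pool <- params$vesicle_pool_NRRP * as.integer(n_contacts)
  list(available = pool, u = 0, t_last = 0, pool = pool)
}

#' Calcium scaling of release probability
#'
#' Hill-type scaling of the utilisation parameter with extracellular
#' calcium, normalised so that the scaling equals 1 at the 2.0 mM in-vitro
#' reference concentration: monotone increasing in calcium.
#'
#' @param calcium_Cao Extracellular calcium concentration (mM).
#' @param hill_coefficient Hill coefficient; 0 disables scaling.
#' @param hill_k Half-saturation constant (mM); package default 2.5.
#' @return Scaling factor (unitless).
#' @export
calcium_scaling <- function(calcium_Cao, hill_coefficient, hill_k = 2.5) {
  if (hill_coefficient <= 0 || hill_k <= 0) return(rep(1, length(calcium_Cao)))
  h <- hill_coefficient
  (calcium_Cao^h / (calcium_Cao^h + hill_k^h)) / (2^h / (2^h + hill_k^h))
}

#' Advance a Tsodyks-Markram connection to a presynaptic spike and release
#'
#' Between events, released vesicles recover independently with time
#' constant `depression_D` and the utilisation variable decays so that, for
#' long inter-spike intervals, the release probability at the next spike
#' relaxes back to the calcium-scaled baseline `U_eff`. At the spike the
#' utilisation facilitates by `U_eff * (1 - u)` and each available vesicle
#' releases independently with probability `u`. Uses R's RNG stream.
#'
#' @param state Connection state from [tm_init_state()] (or a previous call).
#' @param spike_time Time of the presynaptic spike (ms); must not precede
#'   `state$t_last`.
#' @param params A [tm_synapse_params()] object.
#' @param calcium_Cao Extracellular calcium (mM); 2.0 reproduces the
#'   in-vitro reference release probability.
#' @param hill_k Half-saturation constant for the calcium scaling (mM).
#' @return A list with `released` (count) and `state` (updated state).
#' @export
tm_release_step <- function(state, spike_time, params, calcium_Cao = 2.0,
                            hill_k = 2.5) {
  if (state$available < 0) stop("corrupt synapse state: available < 0")
  u_eff <- min(1, params$release_prob_USE *
                 calcium_scaling(calcium_Cao, params$hill_coefficient_UHill,
                                 hill_k))
  dt <- spike_time - state$t_last
  if (dt < 0) stop("spike_time precedes the state's last update")
  missing <- state$pool - state$available
  if (missing > 0 && dt > 0)
    state$available <- state$available +
      rbinom(1, missing, 1 - exp(-dt / params$depression_D))
  state$u <- if (params$facilitation_F > 0)
    state$u * exp(-dt / params$facilitation_F) else 0
  state$u <- state$u + u_eff * (1 - state$u)
  released <- rbinom(1, state$available, state$u)
  state$available <- state$available - released
  state$t_last <- spike_time
  list(released = released, state = state)
}
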