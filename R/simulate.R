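# Network simulation front end over the compiled integration core.

#' Simulation configuration
#'
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms); fixed-step exponential Euler. The 0.1 ms
#'   default matches the sub-millisecond resolution used for stimuli.
#' @param calcium_Cao Extracellular calcium (mM); scales synaptic release
#'   probability through the Hill relation (see [calcium_scaling()]).
#' @param seed Integer seed for all stochastic elements of the run.
#' @param record_voltages Neuron ids whose membrane potential is recorded.
#' @param record_conductances Logical; also record summed excitatory and
#'   inhibitory synaptic conductances of recorded neurons.
#' @param record_stride Record every `record_stride`-th step.
#' @param hill_k Half-saturation constant of the calcium scaling (mM).
#' @param mg Extracellular magnesium (mM) for the NMDA block factor.
#' @param nmda_rise,nmda_decay NMDA conductance kinetics (ms).
#' @param spont_depletes Logical; spontaneous single-vesicle releases
#'   consume a vesicle from the release-ready pool (switchable convention).
#' @param calcium_range Admissible biological range for `calcium_Cao`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration = 1000, dt = 0.1, calcium_Cao = 1.05,
                              seed = 1, record_voltages = integer(0),
                              record_conductances = FALSE, record_stride = 1L,
                              hill_k = 2.5, mg = 1.0,
                              nmda_rise = 0.29, nmda_decay = 43,
                              spont_depletes = TRUE,
                              calcium_range = c(1.0, 2.0)) {
  stopifnot(dt > 0, duration > 0)
  if (calcium_Cao < calcium_range[1] || calcium_Cao > calcium_range[2])
    stop(sprintf("calcium_Cao = %g mM outside configured range [%g, %g]",
                 calcium_Cao, calcium_range[1], calcium_range[2]))
  structure(list(duration = duration, dt = dt, calcium_Cao = calcium_Cao,
                 seed = as.integer(seed), record_voltages = record_voltages,
                 record_conductances = record_conductances,
                 record_stride = as.integer(record_stride),
                 hill_k = hill_k, mg = mg, nmda_rise = nmda_rise,
                 nmda_decay = nmda_decay, spont_depletes = spont_depletes),
            class = "simulation_config")
}

# Assemble pathway/conductance-group arrays shared by internal and external
# pathways. Returns the arrays plus a map pathway name -> index.
.build_pathways <- function(pathway_params, e_rev, i_rev, nmda_rise, nmda_decay) {
  nms <- names(pathway_params)
  np <- length(nms)
  g <- list(taur = numeric(0), taud = numeric(0), erev = numeric(0),
            nmda = logical(0))
  find_grp <- function(taur, taud, erev, nmda) {
    for (k in seq_along(g$taur))
      if (g$taur[k] == taur && g$taud[k] == taud && g$erev[k] == erev &&
          g$nmda[k] == nmda) return(k)
    g$taur <<- c(g$taur, taur); g$taud <<- c(g$taud, taud)
    g$erev <<- c(g$erev, erev); g$nmda <<- c(g$nmda, nmda)
    length(g$taur)
  }
  out <- list(p_use = numeric(np), p_D = numeric(np), p_F = numeric(np),
              p_nrrp = numeric(np), p_uhill = numeric(np),
              p_ghat = numeric(np), p_gratio = numeric(np),
              p_spont = numeric(np), p_quantal_pool = logical(np),
              path_grp = integer(np), path_nmda_grp = integer(np))
  for (i in seq_len(np)) {
    p <- pathway_params[[i]]
    out$p_use[i] <- p$release_prob_USE
    out$p_D[i] <- p$depression_D
    out$p_F[i] <- p$facilitation_F
    out$p_nrrp[i] <- p$vesicle_pool_NRRP
    out$p_uhill[i] <- p$hill_coefficient_UHill
    out$p_ghat[i] <- p$peak_conductance_ghat
    out$p_gratio[i] <- p$conductance_ratio_ghat_ratio
    out$p_spont[i] <- p$spontaneous_rate
    out$p_quantal_pool[i] <- isTRUE(p$quantal_pool)
    erev <- if (p$inhibitory) i_rev else e_rev
    out$path_grp[i] <- find_grp(p$rise_tau, p$decay_tau, erev, FALSE)
    out$path_nmda_grp[i] <-
      if (!p$inhibitory && p$conductance_ratio_ghat_ratio > 0)
        find_grp(nmda_rise, nmda_decay, e_rev, TRUE) else 0L
  }
  out$grp_taur <- g$taur; out$grp_taud <- g$taud
  out$grp_erev <- g$erev; out$grp_nmda <- g$nmda
  out$path_index <- setNames(seq_len(np), nms)
  out
}

#' Simulate the surrogate network
#'
#' Integrates the conductance-based LIF network with stochastic
#' multivesicular Tsodyks-Markram synapses using fixed-step exponential
#' Euler. Runs are bit-reproducible given the configuration seed.
#'
#' @param connectome A [build_surrogate()] connectome (possibly
#'   [disconnect()]ed or [lesion()]ed).
#' @param config A [simulation_config()].
#' @param ou_g0,ou_sigma Per-neuron OU conductance injection mean and sd
#'   (nS); scalars are recycled. Zero disables the injection.
#' @param ou_tau,ou_reversal OU time constant (ms) and reversal (mV).
#' @param current_pulses Data frame of somatic current steps with columns
#'   `neuron`, `amplitude_nA`, `onset_ms`, `duration_ms`, `ramp_ms` (linear
#'   ramp back to zero at offset).
#' @param external External spike sources: a list with `spikes` (data frame
#'   `fiber`, `time_ms`), `edges` (data frame `fiber`, `post`, `nsyn`,
#'   `delay`, `pathway`) and optionally `pathway_params` for pathways not in
#'   the connectome.
#' @param tonic_g,tonic_reversal Optional per-neuron tonic conductance (nS)
#'   and its reversal (mV).
#' @param v_init Initial membrane potential (mV); defaults to each
#'   population's leak reversal.
#'
#' @return An object of class `spike_recording`: list with `spikes` (data
#'   frame `neuron_id`, `time_ms`, sorted by time), `duration`,
#'   `population_index`, and (when requested) `voltages`/`g_exc`/`g_inh`
#'   matrices with a `time_ms` attribute.
#' @export
simulate_network <- function(connectome, config,
                             ou_g0 = 0, ou_sigma = 0, ou_tau = 3,
                             ou_reversal = 0,
                             current_pulses = NULL, external = NULL,
                             tonic_g = 0, tonic_reversal = 0,
                             v_init = NULL) {
  nn <- connectome$neurons
  n <- nrow(nn)
  pops <- connectome$populations
  pop_of <- match(nn$population, vapply(pops, function(p) p$name, character(1)))
  par_of <- function(field)
    vapply(pops, function(p) p$neuron_params[[field]], numeric(1))[pop_of]

  e_rev <- pops[[1]]$neuron_params$excitatory_reversal
  i_rev <- pops[[1]]$neuron_params$inhibitory_reversal

  pparams <- connectome$pathway_params
  if (!is.null(external$pathway_params))
    pparams <- c(pparams,
                 external$pathway_params[setdiff(names(external$pathway_params),
                                                 names(pparams))])
  pw <- .build_pathways(pparams, e_rev, i_rev, config$nmda_rise,
                        config$nmda_decay)

  ed <- connectome$edges
  edge_pre <- ed$pre; edge_post <- ed$post
  edge_nsyn <- as.numeric(ed$nsyn); edge_delay <- as.numeric(ed$delay)
  edge_path <- unname(pw$path_index[ed$pathway])

  n_ext <- 0L
  ext_src <- integer(0); ext_t <- numeric(0)
  if (!is.null(external)) {
    ee <- external$edges
    n_ext <- max(c(ee$fiber, external$spikes$fiber, 0L))
    edge_pre <- c(edge_pre, n + ee$fiber)
    edge_post <- c(edge_post, ee$post)
    edge_nsyn <- c(edge_nsyn, as.numeric(ee$nsyn))
    edge_delay <- c(edge_delay, as.numeric(ee$delay))
    edge_path <- c(edge_path, unname(pw$path_index[ee$pathway]))
    sp <- external$spikes[order(external$spikes$time_ms), , drop = FALSE]
    sp <- sp[sp$time_ms >= 0 & sp$time_ms < config$duration, , drop = FALSE]
    ext_src <- n + as.integer(sp$fiber)
    ext_t <- as.numeric(sp$time_ms)
  }
  if (any(is.na(edge_path))) stop("edge pathway without parameters")
  if (length(config$record_voltages) > 0 &&
      !all(config$record_voltages %in% nn$id))
    stop("record_voltages contains ids not present in the connectome")
  if (!is.null(external) &&
      !all(external$edges$post %in% nn$id))
    stop("external edges target ids not present in the connectome")

  vth <- par_of("spike_threshold")
  if (!is.null(nn$vth_offset)) vth <- vth + nn$vth_offset
  net <- list(n = n,
              C = par_of("membrane_capacitance"), gL = par_of("leak_conductance"),
              EL = par_of("leak_reversal"), Vth = vth,
              Vreset = par_of("reset_potential"), tref = par_of("refractory"),
              Eexc = par_of("excitatory_reversal"),
              Einh = par_of("inhibitory_reversal"),
              edge_pre = as.integer(edge_pre), edge_post = as.integer(edge_post),
              edge_nsyn = edge_nsyn, edge_delay = edge_delay,
              edge_path = as.integer(edge_path), n_ext = as.integer(n_ext),
              p_use = pw$p_use, p_D = pw$p_D, p_F = pw$p_F, p_nrrp = pw$p_nrrp,
              p_uhill = pw$p_uhill, p_ghat = pw$p_ghat,
              p_gratio = pw$p_gratio, p_spont = pw$p_spont,
              p_quantal_pool = pw$p_quantal_pool,
              path_grp = pw$path_grp, path_nmda_grp = pw$path_nmda_grp,
              grp_taur = pw$grp_taur, grp_taud = pw$grp_taud,
              grp_erev = pw$grp_erev, grp_nmda = pw$grp_nmda)

  pulses <- matrix(0, 0, 5)
  if (!is.null(current_pulses) && nrow(current_pulses) > 0) {
    ramp <- current_pulses$ramp_ms %||% rep(0, nrow(current_pulses))
    pulses <- cbind(current_pulses$neuron, current_pulses$amplitude_nA,
                    current_pulses$onset_ms, current_pulses$duration_ms, ramp)
  }

  vinit <- if (is.null(v_init)) par_of("leak_reversal") else rep(v_init, length.out = n)

  cfg <- list(dt = config$dt, duration = config$duration,
              seed = as.double(config$seed %% 2^31),
              calcium = config$calcium_Cao, hill_k = config$hill_k,
              mg = config$mg,
              ou_g0 = rep(as.numeric(ou_g0), length.out = n),
              ou_sigma = rep(as.numeric(ou_sigma), length.out = n),
              ou_tau = ou_tau, ou_erev = ou_reversal,
              tonic_g = rep(as.numeric(tonic_g), length.out = n),
              tonic_erev = tonic_reversal,
              pulses = pulses,
              ext_spk_src = as.integer(ext_src), ext_spk_t = ext_t,
              record_v = as.integer(config$record_voltages),
              record_g = isTRUE(config$record_conductances),
              record_stride = config$record_stride,
              spont_depletes = isTRUE(config$spont_depletes),
              v_init = vinit)

  res <- .sim_core(net, cfg)

  spikes <- data.frame(neuron_id = res$spike_id, time_ms = res$spike_t)
  spikes <- spikes[order(spikes$time_ms, spikes$neuron_id), , drop = FALSE]
  rownames(spikes) <- NULL
  rec <- list(spikes = spikes, duration = config$duration,
              population_index = population_index(connectome),
              config = config)
  if (length(config$record_voltages) > 0) {
    tax <- seq(0, by = config$dt * config$record_stride, length.out = nrow(res$v))
    colnames(res$v) <- config$record_voltages
    attr(res$v, "time_ms") <- tax
    rec$voltages <- res$v
    if (isTRUE(config$record_conductances)) {
      colnames(res$ge) <- colnames(res$gi) <- config$record_voltages
      attr(res$ge, "time_ms") <- tax
      attr(res$gi, "time_ms") <- tax
      rec$g_exc <- res$ge
      rec$g_inh <- res$gi
    }
  }
  class(rec) <- "spike_recording"
  rec
}

#' @export
print.spike_recording <- function(x, ...) {
  cat(sprintf("<spike_recording> %d spikes from %d neurons over %g ms\n",
              nrow(x$spikes), length(unique(x$spikes$neuron_id)), x$duration))
  invisible(x)
}

#' Mean firing rate per population
#'
#' @param recording A `spike_recording`.
#' @param t_start Discard spikes before this time (ms), e.g. a settling
#'   transient.
#' @param populations Population names defining the output order; defaults
#'   to the nine canonical populations present in the recording.
#' @return Named numeric vector of mean per-neuron rates (Hz).
#' @export
population_rates <- function(recording, t_start = 0, populations = NULL) {
  pi <- recording$population_index
  if (is.null(populations)) populations <- intersect(population_names(), unique(pi))
  tspan <- (recording$duration - t_start) / 1000
  sp <- recording$spikes[recording$spikes$time_ms >= t_start, , drop = FALSE]
  pop_of_spike <- pi[as.character(sp$neuron_id)]
  n_per <- table(factor(pi, levels = populations))
  cnt <- table(factor(pop_of_spike, levels = populations))
  as.numeric(cnt) / (as.numeric(n_per) * tspan) -> r
  setNames(ifelse(is.finite(r), r, NA_real_), populations)
}

#' Measure somatic input conductance
#'
#' Applies a small hyperpolarising current step to a neuron at rest and
#' returns the steady-state conductance G_in = delta-I / delta-V (the
#' reciprocal of input resistance). For a passive point neuron this equals
#' the leak conductance plus any tonic open synaptic conductance.
#'
#' @param neuron A [neuron_params()] object.
#' @param tonic_g Tonic open synaptic conductance (nS) included in the
#'   neuron's background state.
#' @param tonic_reversal Reversal of the tonic conductance (mV).
#' @param probe_nA Probe step amplitude (nA); must stay subthreshold.
#' @param settle_ms,probe_ms Settling time and probe duration (ms).
#' @return Input conductance G_in (nS).
#' @export
measure_input_conductance <- function(neuron, tonic_g = 0, tonic_reversal = 0,
                                      probe_nA = -0.02, settle_ms = 500,
                                      probe_ms = 500) {
  pop <- population_spec("L5_E", 1, c(0, 1), neuron)
  con <- structure(list(
    neurons = data.frame(id = 1L, population = "L5_E", class = "E",
                         depth = 0.5, x = 0, y = 0),
    edges = data.frame(pre = integer(0), post = integer(0), nsyn = integer(0),
                       delay = numeric(0), pathway = character(0)),
    pathway_params = default_pathway_params(), populations = list(pop)),
    class = "connectome")
  cfg <- simulation_config(duration = settle_ms + probe_ms, dt = 0.1,
                           calcium_Cao = 2.0, seed = 1, record_voltages = 1L)
  rec <- simulate_network(con, cfg,
                          current_pulses = data.frame(
                            neuron = 1, amplitude_nA = probe_nA,
                            onset_ms = settle_ms, duration_ms = probe_ms,
                            ramp_ms = 0),
                          tonic_g = tonic_g, tonic_reversal = tonic_reversal)
  if (nrow(rec$spikes) > 0)
    stop("neuron spiked during the probe; reduce the probe amplitude")
  tax <- attr(rec$voltages, "time_ms")
  v0 <- mean(rec$voltages[tax > settle_ms - 50 & tax <= settle_ms, 1])
  v1 <- mean(rec$voltages[tax > settle_ms + probe_ms - 50, 1])
  abs(probe_nA * 1000) / abs(v1 - v0)
}

#' Find the rheobase current of a neuron
#'
#' Bisection on the amplitude of a 500 ms somatic step current: the
#' returned value elicits at least one spike while `value * (1 - tol)`
#' elicits none. A neuron that fires spontaneously at zero current is
#' reported with rheobase 0 and attribute `spontaneous = TRUE`.
#'
#' @param neuron A [neuron_params()] object.
#' @param tol Relative tolerance of the bisection (default 1\%).
#' @param step_ms Step duration (ms).
#' @param max_nA Upper search bound (nA).
#' @return Rheobase (nA) with attribute `spontaneous`.
#' @export
find_rheobase <- function(neuron, tol = 0.01, step_ms = 500, max_nA = 5) {
  pop <- population_spec("L5_E", 1, c(0, 1), neuron)
  con <- structure(list(
    neurons = data.frame(id = 1L, population = "L5_E", class = "E",
                         depth = 0.5, x = 0, y = 0),
    edges = data.frame(pre = integer(0), post = integer(0), nsyn = integer(0),
                       delay = numeric(0), pathway = character(0)),
    pathway_params = default_pathway_params(), populations = list(pop)),
    class = "connectome")
  spikes_at <- function(amp) {
    cfg <- simulation_config(duration = 100 + step_ms, dt = 0.1,
                             calcium_Cao = 2.0, seed = 1)
    rec <- simulate_network(con, cfg,
                            current_pulses = data.frame(
                              neuron = 1, amplitude_nA = amp, onset_ms = 100,
                              duration_ms = step_ms, ramp_ms = 0))
    nrow(rec$spikes) > 0
  }
  if (spikes_at(0))
    return(structure(0, spontaneous = TRUE))
  lo <- 0
  hi <- neuron$leak_conductance *
    (neuron$spike_threshold - neuron$leak_reversal) / 1000
  while (!spikes_at(hi)) {
    hi <- hi * 2
    if (hi > max_nA) stop("no spike up to the configured maximum current")
  }
  while ((hi - lo) > tol * hi) {
    mid <- (hi + lo) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  structure(hi, spontaneous = FALSE)
}
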