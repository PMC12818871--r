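# Pathway-level calibration loops: PSP mean/CV -> (ghat, NRRP), and
# spontaneous release rate -> mPSC frequency.

# Build a battery of independent in silico pairs: one external fiber per
# postsynaptic cell, single contact, candidate pathway parameters.
.pair_battery <- function(n_pairs, pathway, post_neuron) {
  pop <- population_spec("L5_E", n_pairs, c(0, 1), post_neuron)
  structure(list(
    neurons = data.frame(id = seq_len(n_pairs), population = "L5_E",
                         class = "E", depth = 0.5, x = 0, y = 0),
    edges = data.frame(pre = integer(0), post = integer(0), nsyn = integer(0),
                       delay = numeric(0), pathway = character(0)),
    pathway_params = list(candidate = pathway),
    populations = list(pop)), class = "connectome")
}

#' Measure pathway PSP amplitude statistics
#'
#' Reproduces the paired-recording protocol in silico: postsynaptic cells
#' resting at -70 mV receive single presynaptic action potentials through
#' one synaptic contact; the somatic PSP amplitude (peak deviation from the
#' pre-spike baseline) is measured over repetitions spaced widely enough
#' for short-term plasticity to recover.
#'
#' @param pathway A [tm_synapse_params()] candidate.
#' @param n_pairs,n_reps Number of sampled pairs and repetitions per pair.
#' @param calcium_Cao Calcium for the protocol (2.0 mM, in-vitro).
#' @param inter_rep_ms Spacing of repetitions (ms).
#' @param seed Integer seed.
#' @param aggregate `"pairs_first"`: CV across repetitions per pair, then
#'   averaged over pairs (default); `"pooled"`: CV over all amplitudes.
#' @return List with `mean` (mV), `cv`, and the amplitude matrix
#'   (reps x pairs).
#' @export
measure_psp <- function(pathway, n_pairs = 50, n_reps = 35,
                        calcium_Cao = 2.0, inter_rep_ms = 1000, seed = 1,
                        aggregate = c("pairs_first", "pooled")) {
  aggregate <- match.arg(aggregate)
  post <- neuron_params(leak_reversal = -70)
  con <- .pair_battery(n_pairs, pathway, post)
  dur <- n_reps * inter_rep_ms + 200
  cfg <- simulation_config(duration = dur, calcium_Cao = calcium_Cao,
                           seed = seed, record_voltages = seq_len(n_pairs),
                           record_stride = 2L,
                           calcium_range = c(0.5, 3))
  spk_t <- (seq_len(n_reps) - 1) * inter_rep_ms + 100
  ext <- list(
    spikes = data.frame(fiber = rep(seq_len(n_pairs), each = n_reps),
                        time_ms = rep(spk_t, n_pairs)),
    edges = data.frame(fiber = seq_len(n_pairs), post = seq_len(n_pairs),
                       nsyn = 1, delay = 1, pathway = "candidate"))
  rec <- simulate_network(con, cfg, external = ext)
  tax <- attr(rec$voltages, "time_ms")
  inh <- isTRUE(pathway$inhibitory)
  amps <- matrix(NA_real_, n_reps, n_pairs)
  for (k in seq_len(n_reps)) {
    base_ix <- tax >= spk_t[k] - 20 & tax < spk_t[k]
    resp_ix <- tax >= spk_t[k] & tax < spk_t[k] + 60
    vb <- colMeans(rec$voltages[base_ix, , drop = FALSE])
    vr <- rec$voltages[resp_ix, , drop = FALSE]
    amps[k, ] <- if (inh) vb - apply(vr, 2, min) else apply(vr, 2, max) - vb
  }
  if (aggregate == "pairs_first") {
    cv_pair <- apply(amps, 2, function(a) sd(a) / mean(a))
    cv <- mean(cv_pair[is.finite(cv_pair)])
  } else {
    cv <- sd(amps) / mean(amps)
  }
  list(mean = mean(amps), cv = cv, amplitudes = amps)
}

#' Calibrate peak conductance and vesicle pool to PSP references
#'
#' Iterative bivariate search reproducing the pathway parameterisation
#' loop: the peak conductance scales the mean PSP amplitude while the
#' (integer) size of the release-ready vesicle pool adjusts its
#' coefficient of variation; iteration stops when both match the in-vitro
#' reference within tolerance, or when the pool reaches the univesicular
#' lower bound (flagged), in which case the boundary solution is returned.
#'
#' @param pathway Starting [tm_synapse_params()].
#' @param target_mean Target mean PSP amplitude (mV).
#' @param target_cv Target CV of the PSP amplitude.
#' @param n_pairs,n_reps,inter_rep_ms,seed Protocol parameters (see
#'   [measure_psp()]).
#' @param tol_mean,tol_cv Relative tolerances (defaults 5\% and 10\%).
#' @param max_iter Iteration cap.
#' @param max_nrrp Upper bound for the vesicle pool.
#' @return List with `pathway` (calibrated params), `ghat`, `NRRP`,
#'   `measured` (last [measure_psp()] stats), `converged`,
#'   `at_univesicular_bound`, `iterations`.
#' @export
calibrate_synapse_psp <- function(pathway, target_mean, target_cv,
                                  n_pairs = 50, n_reps = 35,
                                  inter_rep_ms = 1000, seed = 1,
                                  tol_mean = 0.05, tol_cv = 0.10,
                                  max_iter = 10, max_nrrp = 48) {
  cur <- pathway
  at_bound <- FALSE
  for (iter in seq_len(max_iter)) {
    m <- measure_psp(cur, n_pairs = n_pairs, n_reps = n_reps,
                     inter_rep_ms = inter_rep_ms, seed = seed + iter - 1)
    ok_mean <- abs(m$mean - target_mean) <= tol_mean * target_mean
    ok_cv <- abs(m$cv - target_cv) <= tol_cv * target_cv
    if (ok_mean && (ok_cv || at_bound))
      return(list(pathway = cur, ghat = cur$peak_conductance_ghat,
                  NRRP = cur$vesicle_pool_NRRP, measured = m,
                  converged = ok_cv, at_univesicular_bound = at_bound,
                  iterations = iter))
    if (!ok_cv) {
      # binomial-release CV scales ~ 1/sqrt(pool); a CV still too low at a
      # pool of one cannot be matched (univesicular lower bound)
      new_n <- round(cur$vesicle_pool_NRRP * (m$cv / target_cv)^2)
      new_n <- max(1L, min(max_nrrp, new_n))
      if (new_n == 1L && m$cv < target_cv) at_bound <- TRUE
      cur$vesicle_pool_NRRP <- as.integer(new_n)
    }
    if (!ok_mean) cur$peak_conductance_ghat <-
        cur$peak_conductance_ghat * target_mean / m$mean
  }
  m <- measure_psp(cur, n_pairs = n_pairs, n_reps = n_reps,
                   inter_rep_ms = inter_rep_ms, seed = seed + max_iter)
  list(pathway = cur, ghat = cur$peak_conductance_ghat,
       NRRP = cur$vesicle_pool_NRRP, measured = m, converged = FALSE,
       at_univesicular_bound = at_bound, iterations = max_iter)
}

#' Calibrate the spontaneous release rate to a target mPSC frequency
#'
#' Simulates the somatic miniature-event count produced by a set of
#' synapses releasing spontaneously at each candidate rate: spontaneous
#' releases are independent Poisson processes per synapse, and releases
#' arriving within the detector's resolution window merge into a single
#' somatic event (coincidence loss). The measured frequency is fitted with
#' a logarithmic function `freq = a * log(rate) + b` and the rate matching
#' the in-vitro reference frequency is interpolated.
#'
#' @param n_synapses Number of synapses converging on the cell.
#' @param target_mpsc_freq Target somatic mPSC frequency (Hz).
#' @param candidate_rates Candidate per-synapse spontaneous rates (Hz).
#' @param duration_s Simulated duration per candidate (s).
#' @param detect_window_ms Detector resolution; events closer than this
#'   merge (0 disables coincidence loss).
#' @param seed Integer seed.
#' @return List with `spontaneous_rate` (Hz), `fit` (coefficients a, b),
#'   `table` (candidate rate vs measured frequency), `extrapolated` flag.
#' @export
calibrate_mpsc <- function(n_synapses, target_mpsc_freq, candidate_rates,
                           duration_s = 100, detect_window_ms = 1,
                           seed = 1) {
  stopifnot(length(candidate_rates) >= 2, all(candidate_rates > 0))
  freq <- with_seed(seed, vapply(candidate_rates, function(r) {
    lambda <- n_synapses * r * duration_s
    k <- rpois(1, lambda)
    if (k == 0) return(0)
    ev <- sort(runif(k, 0, duration_s * 1000))
    detected <- if (detect_window_ms > 0)
      1 + sum(diff(ev) > detect_window_ms) else k
    detected / duration_s
  }, numeric(1)))
  res <- .fit_log_interp(candidate_rates, freq, target_mpsc_freq)
  if (res$extrapolated)
    warning("target mPSC frequency outside the fitted range; extrapolating")
  list(spontaneous_rate = res$rate, fit = res$fit,
       table = data.frame(rate = candidate_rates, mpsc_freq = freq),
       extrapolated = res$extrapolated)
}

# Logarithmic fit freq = a * log(rate) + b and its inversion at a target
# frequency.
.fit_log_interp <- function(rates, freqs, target) {
  fit <- lm(freqs ~ log(rates))
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  rate_hat <- exp((target - b) / a)
  list(rate = rate_hat, fit = c(a = a, b = b),
       extrapolated = rate_hat < min(rates) | rate_hat > max(rates))
}
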