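# Spontaneous and evoked activity metrics: PSTHs, latency/decay criteria,
# evoked ratios, correlations, rate distributions, cell selection.

.gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Peristimulus time histogram
#'
#' Bins spikes of one population (optionally trial-averaged around given
#' stimulus onsets), converts to per-neuron rate (Hz), applies Gaussian
#' smoothing, and optionally normalises by subtracting the pre-stimulus
#' baseline and dividing by the peak (baseline-max normalisation).
#'
#' @param recording A `spike_recording`.
#' @param population Population name, vector of names, or `NULL` for the
#'   whole network.
#' @param bin_ms Bin size (ms); 5 for spontaneous histograms, 1 for tuning
#'   PSTHs by convention.
#' @param sigma_bins Gaussian smoothing sd in bins (0 = raw histogram).
#' @param normalization `"none"` or `"baseline_max"`.
#' @param onsets Stimulus onset times (ms) for trial averaging; `NULL`
#'   treats the whole recording as one trial starting at `window[1]`.
#' @param window Time window relative to onset (ms), `c(pre, post)` with
#'   `pre <= 0`; the pre-onset part defines the baseline.
#' @return Object of class `psth`: `time_ms` (bin centres, relative to
#'   onset), `rate` (smoothed Hz per neuron), `raw` (unsmoothed),
#'   `normalized` (when requested), `baseline`, `bin_ms`, `n_neurons`,
#'   `n_trials`.
#' @export
psth <- function(recording, population = NULL, bin_ms = 5, sigma_bins = 1,
                 normalization = c("none", "baseline_max"),
                 onsets = NULL, window = NULL) {
  normalization <- match.arg(normalization)
  pi <- recording$population_index
  ids <- if (is.null(population)) unique(names(pi)) else
    names(pi)[pi %in% population]
  if (length(ids) == 0) stop("empty population")
  sp <- recording$spikes
  sp <- sp[as.character(sp$neuron_id) %in% ids, , drop = FALSE]
  if (is.null(onsets)) {
    onsets <- 0
    if (is.null(window)) window <- c(0, recording$duration)
  }
  stopifnot(!is.null(window), window[1] <= 0 || is.null(onsets))
  edges <- seq(window[1], window[2], by = bin_ms)
  centers <- edges[-length(edges)] + bin_ms / 2
  counts <- numeric(length(centers))
  for (on in onsets) {
    rel <- sp$time_ms - on
    rel <- rel[rel >= window[1] & rel < window[2]]
    counts <- counts + tabulate(findInterval(rel, edges), length(centers))
  }
  rate <- counts / (length(onsets) * length(ids) * bin_ms / 1000)
  sm <- .gauss_smooth(rate, sigma_bins)
  baseline <- if (any(centers < 0)) mean(sm[centers < 0]) else mean(sm)
  out <- list(time_ms = centers, rate = sm, raw = rate, baseline = baseline,
              bin_ms = bin_ms, sigma_bins = sigma_bins,
              n_neurons = length(ids), n_trials = length(onsets),
              normalization = normalization)
  if (normalization == "baseline_max") {
    shifted <- sm - baseline
    pk <- max(shifted)
    out$normalized <- if (pk > 0) shifted / pk else shifted * 0
  }
  class(out) <- "psth"
  out
}

#' Evoked-response metrics from a PSTH
#'
#' Latency is the first post-onset time at which the smoothed PSTH exceeds
#' baseline + 5\% of (peak - baseline) (mirroring the 5\%-of-peak EPSP
#' latency convention); the 50\%- and 25\%-decay points are the first
#' post-peak times at which the PSTH falls to 50\% and 25\% of
#' (peak - baseline) above baseline. The evoked ratio R_E is peak rate
#' over pre-stimulus baseline rate. All of these are invariant to overall
#' rate scaling except R_E, which is a ratio and hence also
#' scale-invariant.
#'
#' @param x A [psth()] with a pre-onset baseline window.
#' @param stim_onset Onset time on the PSTH's (relative) time axis
#'   (default 0).
#' @return List of class `evoked_metrics`: `latency_ms`, `decay50_ms`,
#'   `decay25_ms`, `R_E`, `peak`, `baseline`, `responsive` flag.
#' @export
evoked_metrics <- function(x, stim_onset = 0) {
  tt <- x$time_ms
  v <- x$rate
  base <- x$baseline
  post <- tt >= stim_onset
  if (!any(post)) stop("no post-onset bins")
  pk_ix <- which(post)[which.max(v[post])]
  peak <- v[pk_ix]
  if (peak <= base)
    return(structure(list(latency_ms = NA_real_, decay50_ms = NA_real_,
                          decay25_ms = NA_real_,
                          R_E = if (base > 0) peak / base else NA_real_,
                          peak = peak, baseline = base, responsive = FALSE),
                     class = "evoked_metrics"))
  amp <- peak - base
  lat_ix <- which(post & v > base + 0.05 * amp)[1]
  cross <- function(frac) {
    after <- which(tt > tt[pk_ix] & v <= base + frac * amp)
    if (length(after) == 0) NA_real_ else tt[after[1]]
  }
  structure(list(latency_ms = tt[lat_ix], decay50_ms = cross(0.5),
                 decay25_ms = cross(0.25),
                 R_E = if (base > 0) peak / base else Inf,
                 peak = peak, baseline = base, responsive = TRUE),
            class = "evoked_metrics")
}

#' Evoked-response criteria check against in-vivo references
#'
#' Applies the population-wise similarity rules: latency no more than 10
#' ms later than the reference, 50\%-decay no more than 10 ms later,
#' 25\%-decay no more than 40 ms later, and no secondary rise (no
#' baseline-normalised PSTH value more than 35\% above baseline after 75
#' ms post-onset). L1_I is excluded. The overall result is the
#' conjunction over included populations.
#'
#' @param model_metrics Named list of [evoked_metrics()] per population.
#' @param reference_metrics Named list (or data frame rows) with
#'   `latency_ms`, `decay50_ms`, `decay25_ms` per population.
#' @param psths Named list of baseline-max-normalised [psth()]s per
#'   population (for the secondary-rise rule).
#' @param lat_tol,d50_tol,d25_tol Lag tolerances (ms).
#' @param secondary_after_ms,secondary_level Secondary-rise window start
#'   and level (fraction of peak above baseline).
#' @param exclude Populations excluded from the tests.
#' @return Object of class `criteria_result`: per-population logical
#'   matrix `pass` (rows latency/decay50/decay25/secondary) and `overall`.
#' @export
criteria_check <- function(model_metrics, reference_metrics, psths,
                           lat_tol = 10, d50_tol = 10, d25_tol = 40,
                           secondary_after_ms = 75, secondary_level = 0.35,
                           exclude = "L1_I") {
  pops <- setdiff(names(model_metrics), exclude)
  missing_ref <- setdiff(pops, names(reference_metrics))
  if (length(missing_ref) > 0)
    stop("missing reference population(s): ",
         paste(missing_ref, collapse = ", "))
  pass <- matrix(NA, 4, length(pops),
                 dimnames = list(c("latency", "decay50", "decay25",
                                   "secondary_rise"), pops))
  for (p in pops) {
    m <- model_metrics[[p]]
    r <- reference_metrics[[p]]
    pass["latency", p] <- isTRUE(m$latency_ms <= r$latency_ms + lat_tol)
    pass["decay50", p] <- isTRUE(m$decay50_ms <= r$decay50_ms + d50_tol)
    pass["decay25", p] <- isTRUE(m$decay25_ms <= r$decay25_ms + d25_tol)
    ps <- psths[[p]]
    late <- ps$time_ms > secondary_after_ms
    nv <- ps$normalized %||% ((ps$rate - ps$baseline) /
                                max(ps$rate - ps$baseline))
    pass["secondary_rise", p] <- !any(nv[late] > secondary_level,
                                      na.rm = TRUE)
  }
  structure(list(pass = pass, overall = all(pass)), class = "criteria_result")
}

#' Ratio of connected to unconnected firing rates
#'
#' @param connected_rates,unconnected_rates Named per-population rate
#'   vectors (Hz).
#' @return Named ratios; 0/0 yields `NaN` and x/0 yields `Inf`, both
#'   flagged in the `undefined` attribute.
#' @export
rcu_ratio <- function(connected_rates, unconnected_rates) {
  r <- connected_rates / unconnected_rates
  attr(r, "undefined") <- !is.finite(r)
  r
}

#' Correlation between E and I population histograms
#'
#' Pearson correlation between the Gaussian-smoothed binned spike-count
#' histograms of excitatory and inhibitory neurons, per layer and overall.
#'
#' @param recording A `spike_recording`.
#' @param bin_ms Bin size (ms; default 5).
#' @param sigma_bins Gaussian smoothing sd (bins; default 1).
#' @return Named vector of r values (`overall`, then one per layer with
#'   both E and I populations).
#' @export
ei_correlation <- function(recording, bin_ms = 5, sigma_bins = 1) {
  pi <- recording$population_index
  edges <- seq(0, recording$duration, by = bin_ms)
  hist_of <- function(ids) {
    sp <- recording$spikes
    tv <- sp$time_ms[as.character(sp$neuron_id) %in% ids]
    .gauss_smooth(tabulate(findInterval(tv, edges), length(edges) - 1),
                  sigma_bins)
  }
  e_ids <- names(pi)[grepl("_E$", pi)]
  i_ids <- names(pi)[grepl("_I$", pi)]
  out <- c(overall = cor(hist_of(e_ids), hist_of(i_ids)))
  layers <- intersect(c("L23", "L4", "L5", "L6"),
                      unique(sub("_.*", "", pi)))
  for (ly in layers) {
    e <- names(pi)[pi == paste0(ly, "_E")]
    i <- names(pi)[pi == paste0(ly, "_I")]
    if (length(e) > 0 && length(i) > 0)
      out[ly] <- cor(hist_of(e), hist_of(i))
  }
  out
}

#' Power spectrum of the population rate
#'
#' One-sided periodogram of the mean-subtracted binned network rate,
#' reported as relative power.
#'
#' @param recording A `spike_recording`.
#' @param bin_ms Bin size (ms).
#' @return Data frame `freq_Hz`, `power` (summing to 1).
#' @export
rate_spectrum <- function(recording, bin_ms = 5) {
  edges <- seq(0, recording$duration, by = bin_ms)
  h <- tabulate(findInterval(recording$spikes$time_ms, edges),
                length(edges) - 1)
  h <- h - mean(h)
  n <- length(h)
  sp <- Mod(fft(h))^2
  half <- seq(2, floor(n / 2) + 1)
  fr <- (half - 1) / (n * bin_ms / 1000)
  pw <- sp[half]
  data.frame(freq_Hz = fr, power = pw / sum(pw))
}

#' Firing-rate distribution statistics per population
#'
#' Reports the mean rate including silent neurons, sparsity (the
#' proportion of neurons spiking at least once) and, for the non-zero
#' rates, maximum-likelihood lognormal parameters, reflecting the
#' long-tailed, approximately lognormal rate distributions of cortical
#' populations.
#'
#' @param recording A `spike_recording`.
#' @param t_start Discard spikes before this time (ms).
#' @return Data frame per population: `population`, `mean_rate_Hz`,
#'   `sparsity`, `lognorm_mu`, `lognorm_sigma`, `n`.
#' @export
rate_distribution_stats <- function(recording, t_start = 0) {
  pi <- recording$population_index
  tspan <- (recording$duration - t_start) / 1000
  sp <- recording$spikes[recording$spikes$time_ms >= t_start, ]
  cnt <- table(factor(as.character(sp$neuron_id), levels = names(pi)))
  rate <- as.numeric(cnt) / tspan
  do.call(rbind, lapply(split(seq_along(pi), pi), function(ix) {
    r <- rate[ix]
    nz <- r[r > 0]
    ln <- if (length(nz) >= 2 && sd(log(nz)) > 0)
      tryCatch(MASS::fitdistr(nz, "lognormal")$estimate,
               error = function(e) c(meanlog = mean(log(nz)),
                                     sdlog = sd(log(nz))))
    else c(meanlog = if (length(nz)) log(nz[1]) else NA_real_, sdlog = 0)
    data.frame(population = pi[ix[1]], mean_rate_Hz = mean(r),
               sparsity = mean(r > 0), lognorm_mu = unname(ln[1]),
               lognorm_sigma = unname(ln[2]), n = length(ix))
  })) -> out
  rownames(out) <- NULL
  out
}

#' Select layer 2/3 cells for subthreshold response averaging
#'
#' Applies the three inclusion criteria of the whisker-hold analysis:
#' (1) the cell stays subthreshold (no spikes) during the stimulus and in
#' flanking windows, in both control and perturbed runs; (2) the cell is
#' innervated by at least one active input fiber; (3) the derivative of
#' its control voltage trace crosses a threshold (1 mV/ms) within a short
#' window after stimulus onset. Averaging is then done across cells, not
#' trials.
#'
#' @param control,opto `spike_recording`s with voltage traces of the
#'   candidate cells (the `opto` recording may be `NULL` to skip the
#'   second condition of criterion 1).
#' @param candidate_ids Cell ids to consider.
#' @param innervated_ids Cells innervated by at least one active fiber.
#' @param stim_window `c(onset, offset)` of the stimulus (ms).
#' @param flank_ms Width of the flanking windows (ms).
#' @param dvdt_threshold Voltage-derivative threshold (mV/ms).
#' @param dvdt_window_ms Window after onset for criterion 3 (ms).
#' @return Integer vector of selected cell ids.
#' @export
select_l23_cells <- function(control, opto = NULL, candidate_ids,
                             innervated_ids, stim_window,
                             flank_ms = 200, dvdt_threshold = 1,
                             dvdt_window_ms = 20) {
  lo <- stim_window[1] - flank_ms
  hi <- stim_window[2] + flank_ms
  spiked_in <- function(rec, id) {
    sp <- rec$spikes
    any(sp$neuron_id == id & sp$time_ms >= lo & sp$time_ms <= hi)
  }
  tax <- attr(control$voltages, "time_ms")
  dt <- diff(tax[1:2])
  keep <- vapply(candidate_ids, function(id) {
    if (!(id %in% innervated_ids)) return(FALSE)
    if (spiked_in(control, id)) return(FALSE)
    if (!is.null(opto) && spiked_in(opto, id)) return(FALSE)
    col <- as.character(id)
    if (!col %in% colnames(control$voltages)) return(FALSE)
    v <- control$voltages[, col]
    win <- tax >= stim_window[1] & tax <= stim_window[1] + dvdt_window_ms
    dv <- diff(v[win]) / dt
    any(dv > dvdt_threshold)
  }, logical(1))
  candidate_ids[keep]
}
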