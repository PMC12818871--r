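# Three-step sensory-input pipeline: a stimulus field rho evaluated at
# fiber locations, an optional kinetic transfer function upsilon, and a
# stochastic spiking process psi.

#' Build a set of thalamic input fibers
#'
#' Fibers are laid out uniformly at random over a square flat-space patch;
#' their linear position along a grating axis is the projection of the flat
#' location onto that axis. For the whisker-hold paradigm each fiber is
#' assigned one of four kinetic transfer functions with the reported
#' fractions (11\% position, 58\% velocity, 11\% acceleration, 20\%
#' direction).
#'
#' @param n Number of fibers.
#' @param patch_um Side of the flat patch (um).
#' @param transfer_fractions Named fractions for `pos`, `vel`, `acc`,
#'   `dir`; `NULL` assigns the identity transfer to all fibers.
#' @param grating_axis Unit-vector angle (radians) of the grating drift
#'   axis used for the linear position.
#' @param seed Integer seed.
#' @return Data frame with columns `fiber`, `x`, `y`, `l` (linear position,
#'   um) and `transfer`.
#' @export
thalamic_fibers <- function(n, patch_um = 460,
                            transfer_fractions = NULL,
                            grating_axis = 0, seed = 1) {
  with_seed(seed, {
    x <- runif(n, 0, patch_um)
    y <- runif(n, 0, patch_um)
    l <- x * cos(grating_axis) + y * sin(grating_axis)
    transfer <- rep("identity", n)
    if (!is.null(transfer_fractions)) {
      stopifnot(abs(sum(transfer_fractions) - 1) < 1e-6)
      transfer <- sample(rep(names(transfer_fractions),
                             times = round(transfer_fractions * n))[
                               seq_len(n)])
      transfer[is.na(transfer)] <- "vel"
    }
    data.frame(fiber = seq_len(n), x = x, y = y, l = l, transfer = transfer,
               stringsAsFactors = FALSE)
  })
}

#' Default whisker-hold transfer fractions
#' @return Named numeric vector (pos, vel, acc, dir).
#' @export
whisker_transfer_fractions <- function() {
  c(pos = 0.11, vel = 0.58, acc = 0.11, dir = 0.20)
}

#' Replay an in-vivo PSTH through thalamic fibers
#'
#' A uniformly random subset of `round(F_P * n_fibers)` fibers is selected
#' once per experiment; each selected fiber draws one spike time per trial
#' from the PSTH treated as a probability density (an inhomogeneous-Poisson
#' alternative is available behind `mode`).
#'
#' @param psth Data frame with columns `time_ms` (bin left edges, regular
#'   spacing) and `rate_Hz` (non-negative, not all zero).
#' @param fibers Number of fibers or a [thalamic_fibers()] data frame.
#' @param F_P Fraction of fibers activated, in (0, 1].
#' @param n_trials Number of stimulus repetitions.
#' @param inter_trial_ms Interval between trial onsets (ms).
#' @param seed Integer seed.
#' @param mode `"single_spike"` (one draw per fiber per trial, default) or
#'   `"poisson"` (inhomogeneous Poisson with the PSTH as rate).
#' @return Data frame `fiber`, `trial`, `time_ms` (relative to the start of
#'   the experiment); attribute `active_fibers` lists the selected fibers.
#' @export
psth_replay <- function(psth, fibers, F_P = 0.1, n_trials = 10,
                        inter_trial_ms = 1000, seed = 1,
                        mode = c("single_spike", "poisson")) {
  mode <- match.arg(mode)
  stopifnot(nrow(psth) > 0)
  if (any(psth$rate_Hz < 0)) stop("PSTH rates must be non-negative")
  if (all(psth$rate_Hz == 0)) stop("all-zero PSTH")
  n_fib <- if (is.data.frame(fibers)) nrow(fibers) else as.integer(fibers)
  stopifnot(F_P > 0, F_P <= 1)
  bw <- if (nrow(psth) > 1) diff(psth$time_ms[1:2]) else 1
  with_seed(seed, {
    active <- sort(sample.int(n_fib, round(F_P * n_fib)))
    pr <- psth$rate_Hz / sum(psth$rate_Hz)
    out <- lapply(seq_len(n_trials), function(tr) {
      off <- (tr - 1) * inter_trial_ms
      if (mode == "single_spike") {
        bins <- sample.int(nrow(psth), length(active), replace = TRUE,
                           prob = pr)
        data.frame(fiber = active, trial = tr,
                   time_ms = off + psth$time_ms[bins] + runif(length(active), 0, bw))
      } else {
        do.call(rbind, lapply(active, function(f) {
          k <- rpois(nrow(psth), psth$rate_Hz * bw / 1000)
          ts <- rep(psth$time_ms, k) + runif(sum(k), 0, bw)
          if (length(ts) == 0) return(NULL)
          data.frame(fiber = f, trial = tr, time_ms = off + sort(ts))
        }))
      }
    })
    res <- do.call(rbind, out)
    res <- res[order(res$time_ms), ]
    rownames(res) <- NULL
    attr(res, "active_fibers") <- active
    res
  })
}

#' Whisker-hold step stimulus
#'
#' The 500 ms whisker-hold paradigm encoded as a step function: the
#' stimulus value is 1 between onset and offset and 0 elsewhere, evaluated
#' on the simulation time grid.
#'
#' @param duration Total duration (ms).
#' @param dt Time step (ms).
#' @param onset,offset Hold interval (ms); the value is 1 on
#'   `[onset, offset)`.
#' @return Numeric vector of the stimulus over time.
#' @export
whisker_hold_step <- function(duration = 3000, dt = 0.1, onset = 2000,
                              offset = 2500) {
  t <- seq(0, duration - dt, by = dt)
  as.numeric(t >= onset & t < offset)
}

#' Kinetic transfer functions of thalamic fibers
#'
#' Maps a whisker-position time series to a firing-rate series according
#' to the fiber's kinetic preference: position (scaled copy), velocity
#' (first difference), acceleration (second difference) or direction
#' (positively rectified first difference). Differences are taken between
#' consecutive samples of the series; negative values are permitted for
#' the velocity and acceleration transfers and are truncated at the
#' spiking stage.
#'
#' @param rho Stimulus time series (e.g. [whisker_hold_step()]).
#' @param kind One of `"pos"`, `"vel"`, `"acc"`, `"dir"`, `"identity"`.
#' @param r_max Rate when the fiber's preferred feature is at its
#'   preferred value (Hz); 150 Hz for the whisker-hold paradigm.
#' @return Numeric rate series (Hz), same length as `rho`.
#' @export
whisker_transfer <- function(rho, kind = c("pos", "vel", "acc", "dir",
                                           "identity"), r_max = 150) {
  kind <- match.arg(kind)
  n <- length(rho)
  lead1 <- c(rho[-1], rho[n])
  lag1 <- c(rho[1], rho[-n])
  switch(kind,
         identity = rho,
         pos = r_max * rho,
         vel = r_max * (lead1 - rho),
         acc = r_max * (lead1 - 2 * rho + lag1),
         dir = r_max * pmax(lead1 - rho, 0))
}

#' Drifting-grating firing-rate field
#'
#' Evaluates the sinusoidal input-rate signal of a linear drifting grating
#' at a fiber's linear position. Contrast is Michelson contrast
#' `|Lmax - Lmin| / (Lmax + Lmin)` of normalised luminances centred on
#' 0.5; luminance maps linearly to rate with anchors `R(0.5) = R_bk`
#' (background rate at zero contrast) and `R(1.0) = R_peak` (peak rate at
#' full contrast), and rates are truncated at zero.
#'
#' @param l Linear position of the fiber within the grating (um).
#' @param t Time (seconds); vectorised.
#' @param C Contrast in \[0, 1\].
#' @param f_temp Temporal frequency (Hz; default 2).
#' @param f_spat Spatial frequency (cycles/um; default 0.001, i.e. 0.03
#'   cycles/degree at a 30 um/degree magnification factor).
#' @param R_peak Peak rate at contrast 1 (Hz).
#' @param R_bk Background rate at contrast 0 (Hz).
#' @return Rate (Hz), vectorised over `t`.
#' @export
grating_rate <- function(l, t, C, f_temp = 2, f_spat = 0.001,
                         R_peak = 10, R_bk = 0.2) {
  if (C < 0 || C > 1) stop("contrast outside [0, 1]")
  l_min <- 0.5 * (1 - C)
  l_max <- 0.5 * (1 + C)
  lum_to_rate <- function(L) R_bk + (L - 0.5) / 0.5 * (R_peak - R_bk)
  r_min <- lum_to_rate(l_min)
  r_max <- lum_to_rate(l_max)
  r <- r_min + 0.5 * (r_max - r_min) *
    (1 + sin(2 * pi * f_temp * t - 2 * pi * f_spat * l))
  pmax(r, 0)
}

#' Adapting Markov spiking process
#'
#' Generates a spike train whose per-step hazard is the requested rate
#' reduced by an adaptation state that increments at each emitted spike
#' and decays exponentially with `tau_adapt`. The hazard carries a
#' mean-field gain `1 / (1 - incr * tau_adapt / 1000)` so that for a
#' constant input rate the long-run emitted rate matches the input.
#'
#' @param rate Rate series (Hz) on the `dt` grid; must be non-negative
#'   (truncate kinetic transfers first).
#' @param tau_adapt Adaptation time constant (ms; default 100).
#' @param dt Time step (ms; default 0.1).
#' @param incr Adaptation increment per spike (Hz).
#' @param seed Integer seed.
#' @return Vector of spike times (ms).
#' @export
adapting_markov_spikes <- function(rate, tau_adapt = 100, dt = 0.1,
                                   incr = 3, seed = 1) {
  if (any(rate < 0)) stop("negative input rates; truncate at 0 first")
  .adapting_markov(as.numeric(rate), dt, tau_adapt, incr, seed %% 2^31)
}

#' Random binary state signal
#'
#' A two-state (down/up) signal alternating at random intervals drawn
#' uniformly between 2 and 7 seconds.
#'
#' @param duration_s Signal duration (seconds).
#' @param seed Integer seed.
#' @param min_interval_s,max_interval_s Dwell-time bounds (seconds).
#' @param start_state Initial state (`"down"` or `"up"`).
#' @return Object of class `binary_signal`: `switch_t` (state-change
#'   times, s, beginning at 0), `states` (state following each switch) and
#'   `duration_s`.
#' @export
binary_signal <- function(duration_s, seed = 1, min_interval_s = 2,
                          max_interval_s = 7, start_state = "down") {
  with_seed(seed, {
    t <- 0
    switch_t <- numeric(0)
    states <- character(0)
    cur <- start_state
    while (t < duration_s) {
      switch_t <- c(switch_t, t)
      states <- c(states, cur)
      t <- t + runif(1, min_interval_s, max_interval_s)
      cur <- if (cur == "down") "up" else "down"
    }
    structure(list(switch_t = switch_t, states = states,
                   duration_s = duration_s), class = "binary_signal")
  })
}

#' State of a binary signal at given times
#'
#' @param signal A [binary_signal()].
#' @param t_s Times (seconds).
#' @return Character vector of states.
#' @export
signal_state <- function(signal, t_s) {
  ix <- findInterval(t_s, signal$switch_t)
  ix[ix < 1] <- 1
  signal$states[ix]
}

#' Encode a binary signal as stimulus-neuron spike trains
#'
#' Rate scheme: each stimulus neuron fires as an independent Poisson
#' process at the state-dependent rate. Synchrony scheme: during up states
#' all neurons share one master Poisson train; during down states each
#' fires independently; rates are equal across states so only synchrony
#' carries the signal.
#'
#' @param signal A [binary_signal()].
#' @param n_stim_neurons Number of stimulus neurons (1 to 1e6).
#' @param scheme `"rate"` or `"sync"`.
#' @param rate_up,rate_down State-dependent rates (Hz). Defaults: 30/10 Hz
#'   for the rate scheme, 20/20 Hz for the synchrony scheme.
#' @param seed Integer seed.
#' @return List of numeric vectors of spike times (seconds), one per
#'   stimulus neuron.
#' @export
binary_code_trains <- function(signal, n_stim_neurons,
                               scheme = c("rate", "sync"),
                               rate_up = NULL, rate_down = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  if (n_stim_neurons < 1 || n_stim_neurons > 1e6)
    stop("n_stim_neurons outside [1, 1e6]")
  if (is.null(rate_up)) rate_up <- if (scheme == "rate") 30 else 20
  if (is.null(rate_down)) rate_down <- if (scheme == "rate") 10 else 20
  segs <- data.frame(start = signal$switch_t,
                     end = c(signal$switch_t[-1], signal$duration_s),
                     state = signal$states)
  pois_seg <- function(rate, a, b) {
    k <- rpois(1, rate * (b - a))
    if (k == 0) numeric(0) else sort(runif(k, a, b))
  }
  with_seed(seed, {
    if (scheme == "rate") {
      lapply(seq_len(n_stim_neurons), function(i) {
        unlist(lapply(seq_len(nrow(segs)), function(s) {
          r <- if (segs$state[s] == "up") rate_up else rate_down
          pois_seg(r, segs$start[s], segs$end[s])
        }))
      })
    } else {
      master <- lapply(seq_len(nrow(segs)), function(s)
        if (segs$state[s] == "up")
          pois_seg(rate_up, segs$start[s], segs$end[s]) else NULL)
      lapply(seq_len(n_stim_neurons), function(i) {
        unlist(lapply(seq_len(nrow(segs)), function(s) {
          if (segs$state[s] == "up") master[[s]]
          else pois_seg(rate_down, segs$start[s], segs$end[s])
        }))
      })
    }
  })
}
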