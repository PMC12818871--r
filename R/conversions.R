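# Small closed-form quantities used when configuring experiments.

#' Probability that a synchronous pattern falls in a time window
#'
#' For synchronous events emitted at a given rate, the probability that
#' one lands in a window of the given length (rate * window, for windows
#' short relative to the inter-event interval).
#'
#' @param rate_hz Pattern rate (Hz).
#' @param window_ms Window length (ms).
#' @return Probability.
#' @export
pattern_window_probability <- function(rate_hz, window_ms) {
  rate_hz * window_ms / 1000
}

#' Convert a spatial frequency from cycles/degree to cycles/um
#'
#' Uses the cortical magnification factor (um of cortex per degree of
#' visual angle; 30 um/degree in rat).
#'
#' @param cycles_per_degree Spatial frequency (cycles/degree).
#' @param magnification_um_per_degree Cortical magnification (um/degree).
#' @return Spatial frequency in cycles/um.
#' @export
spatial_frequency_um <- function(cycles_per_degree,
                                 magnification_um_per_degree = 30) {
  cycles_per_degree / magnification_um_per_degree
}

#' Mid-range to local synapse percentage
#'
#' Percentage by which mid-range synapses increase the intrinsic synapse
#' count of a circuit: `100 * mid_range / local`.
#'
#' @param mid_range,local Synapse counts (any common unit).
#' @return Percentage.
#' @export
midrange_local_percent <- function(mid_range, local) {
  100 * mid_range / local
}
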