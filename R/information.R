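# Mutual information between binned single-cell activity and a binary
# stimulus signal, with a circular-shift shuffle control.

.mi_plugin <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

.mi_of <- function(state01, counts, cap, estimator) {
  counts <- pmin(counts, cap)
  joint <- matrix(0, 2, cap + 1)
  for (s in 0:1) {
    tb <- tabulate(counts[state01 == s] + 1L, cap + 1L)
    joint[s + 1, ] <- tb
  }
  mi <- .mi_plugin(joint)
  if (estimator == "mm") {
    # Miller-Madow bias correction
    n <- sum(joint)
    kxy <- sum(joint > 0); kx <- sum(rowSums(joint) > 0)
    ky <- sum(colSums(joint) > 0)
    mi <- mi - (kxy - kx - ky + 1) / (2 * n * log(2))
  }
  mi
}

#' Mutual information between cell activity and a binary signal
#'
#' Computes the plug-in mutual information between the binary state of
#' each analysis bin and each cell's (capped) spike count in that bin.
#' Significance is assessed against a shuffle control built from circular
#' time-shifts of the signal, which preserve its dwell-time structure: a
#' cell is significant when its MI exceeds the (1 - alpha) quantile of
#' its shuffled MI values. Cells that never spike are excluded.
#'
#' @param signal A [binary_signal()].
#' @param spike_trains List of per-cell spike-time vectors (seconds).
#' @param window `"all_bins"` (every bin of the recording) or
#'   `"first_bin"` (only the first bin after each state change).
#' @param bin_ms Analysis bin (ms; default 50).
#' @param n_shuffles Number of circular shifts (default 100).
#' @param alpha Significance level.
#' @param count_cap Spike counts above this value are capped.
#' @param estimator `"plugin"` or `"mm"` (Miller-Madow corrected).
#' @param seed Integer seed for the shuffle offsets.
#' @return Data frame per analysed cell: `cell`, `mi_bits`,
#'   `mi_shuffle_crit` (the (1-alpha) shuffle quantile), `significant`.
#' @export
mutual_information <- function(signal, spike_trains,
                               window = c("all_bins", "first_bin"),
                               bin_ms = 50, n_shuffles = 100, alpha = 0.05,
                               count_cap = 5,
                               estimator = c("plugin", "mm"), seed = 1) {
  window <- match.arg(window)
  estimator <- match.arg(estimator)
  bin_s <- bin_ms / 1000
  edges <- seq(0, signal$duration_s, by = bin_s)
  n_bins <- length(edges) - 1
  centers <- edges[-length(edges)] + bin_s / 2
  state <- as.integer(signal_state(signal, centers) == "up")
  if (length(unique(state)) < 2)
    stop("fewer than 2 distinct signal states in the analysed span")
  use <- rep(TRUE, n_bins)
  if (window == "first_bin") {
    first_ix <- unique(findInterval(signal$switch_t[-1], edges))
    use <- seq_len(n_bins) %in% (first_ix + 1L)
    use[is.na(use)] <- FALSE
  }
  counts_of <- function(tr) tabulate(findInterval(tr, edges), n_bins)
  with_seed(seed, {
    shifts <- sample.int(n_bins - 1, n_shuffles, replace = TRUE)
    rows <- lapply(seq_along(spike_trains), function(ci) {
      tr <- spike_trains[[ci]]
      if (length(tr) == 0) return(NULL)
      cnt <- counts_of(tr)
      mi <- .mi_of(state[use], cnt[use], count_cap, estimator)
      null_mi <- vapply(shifts, function(sh) {
        st <- c(state[(sh + 1):n_bins], state[seq_len(sh)])
        .mi_of(st[use], cnt[use], count_cap, estimator)
      }, numeric(1))
      crit <- quantile(null_mi, 1 - alpha, names = FALSE)
      data.frame(cell = ci, mi_bits = mi, mi_shuffle_crit = crit,
                 significant = mi > crit)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
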