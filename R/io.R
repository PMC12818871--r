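# Tab-separated and YAML interchange formats.

#' Write / read a spike table
#'
#' Tab-separated with header `neuron_id`, `time_ms`.
#' @param recording A `spike_recording` (or a data frame with those
#'   columns).
#' @param path File path.
#' @return `read_spikes` returns a data frame sorted by time.
#' @export
write_spikes <- function(recording, path) {
  df <- if (inherits(recording, "spike_recording")) recording$spikes
  else recording
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- read.delim(path)
  df[order(df$time_ms), , drop = FALSE]
}

#' Write / read an edge list
#'
#' Tab-separated with header `pre_id`, `post_id`, `nsyn`, `delay_ms`,
#' `pathway`.
#' @param edges Edge data frame (columns `pre`, `post`, `nsyn`, `delay`,
#'   `pathway`) or a connectome.
#' @param path File path.
#' @export
write_edges <- function(edges, path) {
  if (inherits(edges, "connectome")) edges <- edges$edges
  out <- data.frame(pre_id = edges$pre, post_id = edges$post,
                    nsyn = edges$nsyn, delay_ms = edges$delay,
                    pathway = edges$pathway)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- read.delim(path)
  data.frame(pre = df$pre_id, post = df$post_id, nsyn = df$nsyn,
             delay = df$delay_ms, pathway = df$pathway)
}

#' Read a reference PSTH table
#'
#' Tab-separated with columns `time_ms`, `rate_Hz`.
#' @param path File path.
#' @return Data frame.
#' @export
read_psth_table <- function(path) read.delim(path)

#' Read / write target firing-rate vectors
#'
#' Tab-separated with columns `population`, `rate_Hz`.
#' @param path File path.
#' @param rates An [fr_vector()] (for writing).
#' @param role Role given to the read vector.
#' @export
read_fr_vector <- function(path, role = "V_FR") {
  df <- read.delim(path)
  fr_vector(df$rate_Hz[match(population_names(), df$population)], role = role)
}

#' @rdname read_fr_vector
#' @export
write_fr_vector <- function(rates, path) {
  write.table(data.frame(population = names(rates),
                         rate_Hz = as.numeric(rates)),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise an OU injection table to / from a YAML configuration block
#'
#' The block maps population names to `{OU_mu, OU_sigma}` percent values,
#' with the shared `R_OU`, `tau` and `reversal` alongside.
#'
#' @param table An [ou_injection_table()].
#' @param path YAML file path.
#' @export
write_ou_table <- function(table, path) {
  block <- list(R_OU = table$R_OU,
                tau = table$params[[1]]$tau,
                reversal = table$params[[1]]$reversal,
                populations = lapply(table$params, function(p)
                  list(OU_mu = p$OU_mu, OU_sigma = p$OU_sigma)))
  yaml::write_yaml(list(ou_injection = block), path)
  invisible(path)
}

#' @rdname write_ou_table
#' @export
read_ou_table <- function(path) {
  y <- yaml::read_yaml(path)$ou_injection
  mus <- vapply(y$populations, function(p) p$OU_mu, numeric(1))
  ou_injection_table(setNames(mus, names(y$populations)), R_OU = y$R_OU,
                     tau = y$tau %||% 3, reversal = y$reversal %||% 0)
}
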