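# Ornstein-Uhlenbeck somatic conductance injection (missing-input
# compensation).

#' OU injection parameters for one population
#'
#' Mean and standard deviation of the compensating conductance injection,
#' expressed as percentages of a cell's input conductance G_in at rest. The
#' OU process dg/dt = -(g - g0)/tau + sqrt(D) chi(t) is parameterised by its
#' stationary standard deviation sigma, with diffusion coefficient
#' D = 2 sigma^2 / tau.
#'
#' @param OU_mu Mean, percent of G_in.
#' @param OU_sigma Standard deviation, percent of G_in.
#' @param tau Correlation time constant (ms); 3 ms default, the
#'   point-conductance convention for aggregated excitatory background.
#' @param reversal Reversal potential (mV); the injection is excitatory.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(OU_mu, OU_sigma, tau = 3, reversal = 0) {
  stopifnot(tau > 0, OU_sigma >= 0)
  structure(list(OU_mu = OU_mu, OU_sigma = OU_sigma, tau = tau,
                 reversal = reversal), class = "ou_params")
}

#' Per-population OU injection table
#'
#' Builds the population -> parameter map under the ratio constraint
#' OU_sigma = OU_mu * R_OU, which ties the noisiness of the compensation to
#' a single meta-parameter.
#'
#' @param OU_mu Named numeric vector of means (percent of G_in) keyed by
#'   population name.
#' @param R_OU Ratio OU_sigma / OU_mu.
#' @param tau,reversal Passed to [ou_params()].
#' @return An object of class `ou_injection_table`.
#' @export
ou_injection_table <- function(OU_mu, R_OU = 0.4, tau = 3, reversal = 0) {
  stopifnot(!is.null(names(OU_mu)), R_OU >= 0)
  tab <- lapply(OU_mu, function(m) ou_params(m, m * R_OU, tau, reversal))
  structure(list(params = tab, R_OU = R_OU), class = "ou_injection_table")
}

#' @export
print.ou_injection_table <- function(x, ...) {
  mus <- vapply(x$params, function(p) p$OU_mu, numeric(1))
  cat("<ou_injection_table> R_OU =", x$R_OU, "\n")
  print(round(mus, 2))
  invisible(x)
}

#' Generate an OU conductance trace
#'
#' Exact discretisation of the stationary OU process:
#' `g(t+dt) = g0 + (g(t) - g0) exp(-dt/tau) + sigma sqrt(1 - exp(-2 dt/tau)) N(0,1)`.
#' The returned trace is the pre-clipping process (stationary mean `g0`,
#' stationary sd `sigma`); negative excursions are clipped at zero only at
#' the point of injection into a cell.
#'
#' @param g0 Stationary mean (nS).
#' @param sigma Stationary standard deviation (nS).
#' @param tau Time constant (ms).
#' @param dt Step (ms); must satisfy dt <= tau.
#' @param duration Length of the trace (ms).
#' @param seed Integer seed (one independent stream per neuron is obtained
#'   by giving each neuron its own sub-seed).
#' @return Numeric vector of conductances (nS), starting at `g0`.
#' @export
ou_trace <- function(g0, sigma, tau = 3, dt = 0.1, duration = 1000, seed = 1) {
  stopifnot(g0 >= 0, sigma >= 0, tau > 0, dt > 0, duration > 0)
  if (dt > tau) stop("dt > tau: discretisation invalid")
  n <- round(duration / dt)
  if (sigma == 0) return(rep(g0, n + 1))
  a <- exp(-dt / tau)
  b <- sigma * sqrt(1 - a^2)
  with_seed(seed, {
    innov <- rnorm(n) * b
    # g_k - g0 = a * (g_{k-1} - g0) + innov_k : AR(1) recursion
    dev <- stats::filter(innov, a, method = "recursive")
    c(g0, g0 + as.numeric(dev))
  })
}

#' Scale OU percentages to a cell's conductances
#'
#' @param params An [ou_params()] object.
#' @param G_in Input conductance of the cell (nS), from
#'   [measure_input_conductance()].
#' @return List with `g0` and `sigma` in nS.
#' @export
scale_to_cell <- function(params, G_in) {
  if (G_in <= 0) stop("G_in must be positive")
  list(g0 = params$OU_mu / 100 * G_in, sigma = params$OU_sigma / 100 * G_in)
}

# Expand an ou_injection_table into per-neuron g0/sigma vectors for
# simulate_network(), given per-population input conductances.
.ou_vectors <- function(connectome, table, G_in_by_pop) {
  nn <- connectome$neurons
  g0 <- numeric(nrow(nn)); sg <- numeric(nrow(nn))
  for (pop in names(table$params)) {
    sel <- nn$population == pop
    if (!any(sel)) next
    sc <- scale_to_cell(table$params[[pop]], G_in_by_pop[[pop]])
    g0[sel] <- sc$g0; sg[sel] <- sc$sigma
  }
  list(g0 = g0, sigma = sg, tau = table$params[[1]]$tau,
       reversal = table$params[[1]]$reversal)
}

#' Input conductance of each population at rest
#'
#' @param connectome A connectome.
#' @return Named numeric vector of G_in (nS) per population.
#' @export
population_input_conductance <- function(connectome) {
  vapply(connectome$populations, function(p)
    measure_input_conductance(p$neuron_params), numeric(1)) |>
    setNames(vapply(connectome$populations, function(p) p$name, character(1)))
}
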