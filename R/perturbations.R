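# Optogenetic stimulation with depth-dependent light attenuation, and
# connectome lesions.

#' Effective light attenuation coefficient
#'
#' Modified Beer-Lambert approximation for scattering tissue:
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`.
#'
#' @param mu_a Absorption coefficient (1/mm).
#' @param mu_s_prime Reduced scattering coefficient (1/mm).
#' @return Effective attenuation coefficient (1/mm).
#' @export
mu_eff <- function(mu_a, mu_s_prime) {
  if (any(mu_a <= 0) || any(mu_s_prime < 0)) stop("non-positive coefficients")
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Built-in optical tissue coefficients by wavelength
#'
#' The two wavelength entries used by the recreated experiments: 595 nm
#' (yellow; mu_a = 0.49/mm, mu_s' = 4.12/mm) and 470 nm (blue;
#' mu_a = 0.46/mm, mu_s' = 5.38/mm).
#'
#' @param wavelength_nm 595 or 470.
#' @return List with `mu_a` and `mu_s_prime` (1/mm).
#' @export
optical_coefficients <- function(wavelength_nm) {
  tab <- list(`595` = list(mu_a = 0.49, mu_s_prime = 4.12),
              `470` = list(mu_a = 0.46, mu_s_prime = 5.38))
  key <- as.character(wavelength_nm)
  if (!key %in% names(tab))
    stop("no built-in coefficients for ", wavelength_nm,
         " nm; supply mu_a and mu_s_prime explicitly")
  tab[[key]]
}

#' Light intensity at depth
#'
#' Exponential attenuation `I(d) = I0 * exp(-mu_eff * d)`.
#'
#' @param I0 Surface intensity (any unit; here percent of rheobase).
#' @param mu_eff Effective attenuation coefficient (1/mm).
#' @param d Depth (mm); vectorised.
#' @return Intensity at depth, same unit as `I0`.
#' @export
intensity_at_depth <- function(I0, mu_eff, d) {
  I0 * exp(-mu_eff * d)
}

#' Light-field description for optogenetic stimulation
#'
#' @param I0 Surface intensity as a signed percentage of each cell's
#'   rheobase (negative values hyperpolarise).
#' @param mu_a,mu_s_prime Optical coefficients (1/mm); taken from
#'   [optical_coefficients()] when a `wavelength_nm` is given instead.
#' @param wavelength_nm Optional wavelength with built-in coefficients.
#' @param n_depth_bins Number of depth bins (equal intensity increments).
#' @param ramp_ms Length of the linear off-ramp avoiding rebound spikes.
#' @return Object of class `light_field`.
#' @export
light_field <- function(I0, mu_a = NULL, mu_s_prime = NULL,
                        wavelength_nm = NULL, n_depth_bins = 5,
                        ramp_ms = 100) {
  if (!is.null(wavelength_nm)) {
    oc <- optical_coefficients(wavelength_nm)
    mu_a <- oc$mu_a; mu_s_prime <- oc$mu_s_prime
  }
  stopifnot(mu_a > 0, mu_s_prime > 0, n_depth_bins >= 1, ramp_ms >= 0)
  structure(list(I0 = I0, mu_a = mu_a, mu_s_prime = mu_s_prime,
                 wavelength_nm = wavelength_nm,
                 mu_eff = mu_eff(mu_a, mu_s_prime),
                 n_depth_bins = as.integer(n_depth_bins), ramp_ms = ramp_ms),
            class = "light_field")
}

#' Bin targeted cells by depth with equal intensity increments
#'
#' Bin edges are placed so that consecutive bins span equal increments of
#' light intensity (not of depth) between the shallowest and deepest
#' targeted cell; because attenuation is exponential, bins therefore grow
#' wider with depth. Each cell uses the intensity at its bin's centre (the
#' midpoint of the bin's intensity span). Cells exactly on an edge join
#' the shallower bin.
#'
#' @param depth_um Cell depths (um below the surface).
#' @param n_bins Number of bins.
#' @param light A [light_field()] (for `mu_eff`).
#' @return List with `bin` (assignment per cell), `intensity_rel`
#'   (relative intensity I(bin centre)/I0 per cell), `edges_um`, and
#'   `collapsed` flag (all cells at one depth).
#' @export
depth_bins <- function(depth_um, n_bins, light) {
  d_mm <- depth_um / 1000
  dmin <- min(d_mm); dmax <- max(d_mm)
  collapsed <- FALSE
  if (dmax - dmin < 1e-12) {
    if (n_bins > 1) { collapsed <- TRUE; n_bins <- 1L }
  }
  me <- light$mu_eff
  i_top <- exp(-me * dmin)
  i_bot <- exp(-me * dmax)
  # intensity edges, equally spaced; depth edges are their inverse image
  i_edges <- seq(i_top, i_bot, length.out = n_bins + 1)
  d_edges <- -log(i_edges) / me
  d_edges[1] <- dmin; d_edges[n_bins + 1] <- dmax
  # cell on an edge -> shallower bin: intervals (lo, hi] except the first
  bin <- findInterval(-d_mm, rev(-d_edges), rightmost.closed = TRUE)
  bin <- n_bins + 1L - bin
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  i_centers <- (i_edges[-1] + i_edges[-(n_bins + 1)]) / 2
  list(bin = bin, intensity_rel = i_centers[bin],
       edges_um = d_edges * 1000, collapsed = collapsed)
}

#' Optogenetic current injection waveforms
#'
#' Builds per-cell somatic current pulses with amplitude proportional to
#' each cell's rheobase, scaled by the relative light intensity at the
#' cell's depth bin: `amp = (I0/100) * rheobase * I(d_bin)/I0_surface`. A
#' square pulse with a linear off-ramp (`ramp_ms`) is produced.
#'
#' @param cells Data frame with columns `id`, `depth` (um) and `rheobase`
#'   (nA, from [find_rheobase()]).
#' @param light A [light_field()].
#' @param onset_ms,duration_ms Pulse timing (ms).
#' @return Data frame of current pulses suitable for
#'   [simulate_network()]'s `current_pulses` argument, with an added
#'   `bin` column.
#' @export
opto_injection <- function(cells, light, onset_ms, duration_ms) {
  stopifnot(all(c("id", "depth", "rheobase") %in% names(cells)))
  if (any(is.na(cells$rheobase))) stop("missing rheobase for targeted cells")
  db <- depth_bins(cells$depth, light$n_depth_bins, light)
  data.frame(neuron = cells$id,
             amplitude_nA = light$I0 / 100 * cells$rheobase * db$intensity_rel,
             onset_ms = onset_ms, duration_ms = duration_ms,
             ramp_ms = light$ramp_ms, bin = db$bin)
}

#' Lesion a synaptic pathway
#'
#' Removes all (and only) connections whose presynaptic neuron is in the
#' first selector and whose postsynaptic neuron is in the second,
#' mimicking an exact in silico pathway lesion.
#'
#' @param connectome A connectome.
#' @param pre,post Selectors accepted by [select_neurons()] (population
#'   names, class labels or neuron ids).
#' @return The lesioned connectome.
#' @export
lesion <- function(connectome, pre, post) {
  pre_ids <- select_neurons(connectome, pre)
  post_ids <- select_neurons(connectome, post)
  if (length(pre_ids) == 0 || length(post_ids) == 0) {
    warning("lesion selector resolves to an empty set; no-op")
    return(connectome)
  }
  drop <- connectome$edges$pre %in% pre_ids &
    connectome$edges$post %in% post_ids
  connectome$edges <- connectome$edges[!drop, , drop = FALSE]
  rownames(connectome$edges) <- NULL
  connectome
}
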