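# Surrogate connectome construction and editing.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Build a seeded surrogate connectome
#'
#' Draws a sparse directed synaptic graph over layered populations:
#' connections appear independently with a pairwise probability, carry an
#' integer synapse (contact) count and a conduction delay, and are labelled
#' by the presynaptic-class to postsynaptic-class pathway whose
#' [tm_synapse_params()] they use. Neurons receive a depth sampled uniformly
#' within their population's depth range and a flat (tangential) location
#' uniform over a square patch.
#'
#' @param populations List of [population_spec()] objects (e.g.
#'   [default_populations()]).
#' @param connectivity_rule List with elements `p_conn` (scalar connection
#'   probability in \[0, 1\], or a matrix indexed by population names),
#'   `nsyn_mean` (mean synapse count per connection, >= 1), `delay_range`
#'   (length-2 ms) and optionally `patch_um` (side of the flat patch,
#'   default 460).
#' @param seed Integer seed; the same seed always yields the same edge list.
#' @param pathway_params Named list of [tm_synapse_params()] keyed by
#'   pathway label (`"E->E"` etc.); defaults to [default_pathway_params()].
#'
#' @return An object of class `connectome`: a list with `neurons` (data
#'   frame: id, population, class, depth, x, y), `edges` (data frame: pre,
#'   post, nsyn, delay, pathway), `pathway_params` and `populations`.
#' @export
build_surrogate <- function(populations,
                            connectivity_rule = list(p_conn = 0.05,
                                                     nsyn_mean = 3,
                                                     delay_range = c(1, 3)),
                            seed = 1,
                            pathway_params = default_pathway_params()) {
  if (length(populations) == 0) stop("empty population list")
  counts <- vapply(populations, function(p) p$count, integer(1))
  if (any(counts <= 0)) stop("empty population")
  p_conn <- connectivity_rule$p_conn
  if (is.null(p_conn)) p_conn <- 0.05
  if (any(p_conn < 0) || any(p_conn > 1))
    stop("connection probability outside [0, 1]")
  nsyn_mean <- connectivity_rule$nsyn_mean %||% 3
  delay_range <- connectivity_rule$delay_range %||% c(1, 3)
  patch <- connectivity_rule$patch_um %||% 460

  pop_names <- vapply(populations, function(p) p$name, character(1))
  with_seed(seed, {
    offs <- c(0, cumsum(counts))
    neurons <- do.call(rbind, lapply(seq_along(populations), function(k) {
      p <- populations[[k]]
      data.frame(id = (offs[k] + 1):(offs[k] + p$count),
                 population = p$name, class = p$synapse_class,
                 depth = runif(p$count, p$depth_range[1], p$depth_range[2]),
                 x = runif(p$count, 0, patch), y = runif(p$count, 0, patch),
                 vth_offset = rnorm(p$count,
                                    sd = p$neuron_params$threshold_sd %||% 0),
                 stringsAsFactors = FALSE)
    }))
    edge_list <- vector("list", length(populations)^2)
    ix <- 0
    for (a in seq_along(populations)) {
      for (b in seq_along(populations)) {
        p_ab <- if (is.matrix(p_conn))
          p_conn[pop_names[a], pop_names[b]] else p_conn
        ix <- ix + 1
        if (p_ab <= 0) next
        na <- counts[a]; nb <- counts[b]
        hit <- which(runif(na * nb) < p_ab)
        if (length(hit) == 0) next
        pre <- offs[a] + ((hit - 1) %% na) + 1
        post <- offs[b] + ((hit - 1) %/% na) + 1
        keep <- pre != post
        pre <- pre[keep]; post <- post[keep]
        if (length(pre) == 0) next
        lab <- paste0(populations[[a]]$synapse_class, "->",
                      populations[[b]]$synapse_class)
        edge_list[[ix]] <- data.frame(
          pre = pre, post = post,
          nsyn = 1L + rpois(length(pre), max(0, nsyn_mean - 1)),
          delay = runif(length(pre), delay_range[1], delay_range[2]),
          pathway = lab, stringsAsFactors = FALSE)
      }
    }
    edges <- do.call(rbind, edge_list[!vapply(edge_list, is.null, logical(1))])
    if (is.null(edges))
      edges <- data.frame(pre = integer(0), post = integer(0),
                          nsyn = integer(0), delay = numeric(0),
                          pathway = character(0), stringsAsFactors = FALSE)
    missing_paths <- setdiff(unique(edges$pathway), names(pathway_params))
    if (length(missing_paths) > 0)
      stop("no synapse parameters for pathway(s): ",
           paste(missing_paths, collapse = ", "))
    structure(list(neurons = neurons, edges = edges,
                   pathway_params = pathway_params,
                   populations = populations),
              class = "connectome")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove all recurrent connections
#'
#' Returns a copy of the connectome with zero internal edges; neurons,
#' populations and pathway parameters (and hence any external-input hooks)
#' are untouched. Used to measure unconnected firing rates during
#' compensation calibration.
#'
#' @param connectome A [build_surrogate()] connectome.
#' @return A `connectome` with an empty edge table.
#' @export
disconnect <- function(connectome) {
  connectome$edges <- connectome$edges[integer(0), , drop = FALSE]
  connectome
}

#' Population membership of each neuron
#'
#' @param connectome A connectome.
#' @return Character vector mapping neuron id to population name.
#' @export
population_index <- function(connectome) {
  setNames(connectome$neurons$population, connectome$neurons$id)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d neurons in %d populations, %d edges (%d synapses)\n",
              nrow(x$neurons), length(x$populations), nrow(x$edges),
              sum(x$edges$nsyn)))
  invisible(x)
}

#' Neuron ids belonging to given populations
#'
#' @param connectome A connectome.
#' @param selector Population names (e.g. `"L4_E"`), a synapse class
#'   (`"E"`/`"I"`), or explicit neuron ids (numeric).
#' @return Integer vector of neuron ids.
#' @export
select_neurons <- function(connectome, selector) {
  nn <- connectome$neurons
  if (is.numeric(selector)) return(intersect(as.integer(selector), nn$id))
  if (all(selector %in% c("E", "I"))) return(nn$id[nn$class %in% selector])
  nn$id[nn$population %in% selector]
}
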