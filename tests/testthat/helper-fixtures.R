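# Shared fixtures: small networks and graphs built in code.

# A reduced surrogate (9 populations x n neurons) for fast property tests.
small_surrogate <- function(n_per_pop = 50, seed = 42, p_conn = 0.05) {
  build_surrogate(default_populations(n_per_pop),
                  connectivity_rule = list(p_conn = p_conn, nsyn_mean = 3,
                                           delay_range = c(1, 3)),
                  seed = seed)
}

# A single-population, single-neuron connectome around given neuron params.
one_neuron_connectome <- function(np = neuron_params()) {
  pop <- population_spec("L5_E", 1, c(0, 1), np)
  structure(list(
    neurons = data.frame(id = 1L, population = "L5_E", class = "E",
                         depth = 0.5, x = 0, y = 0),
    edges = data.frame(pre = integer(0), post = integer(0), nsyn = integer(0),
                       delay = numeric(0), pathway = character(0)),
    pathway_params = default_pathway_params(),
    populations = list(pop)), class = "connectome")
}

# Random Erdos-Renyi digraph edge list (no self-loops, no duplicates).
random_digraph <- function(n, p, seed) {
  with_seed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs[runif(nrow(pairs)) < p, ]
  })
}
with_seed <- cortexsim:::with_seed

# Brute-force directed-simplex participation: enumerate node subsets and
# count orderings in which every earlier node sends an edge to every later
# node. Independent of the package's ordered-extension counter.
brute_participation <- function(edges, n, max_dim) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) A[cbind(edges$from, edges$to)] <- TRUE
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  par <- matrix(0, n, max_dim)
  for (m in 2:(max_dim + 1)) {
    if (m > n) break
    for (sub in utils::combn(n, m, simplify = FALSE)) {
      if (sum(A[sub, sub]) < choose(m, 2)) next
      for (p in perms(sub)) {
        ap <- A[p, p]
        if (all(ap[upper.tri(ap)]))
          par[p, m - 1] <- par[p, m - 1] + 1
      }
    }
  }
  par
}

# Complete feed-forward digraph on k nodes (edges i -> j for i < j).
complete_ff <- function(k) {
  idx <- utils::combn(k, 2)
  data.frame(from = idx[1, ], to = idx[2, ])
}
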