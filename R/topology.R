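# Structure-function analysis: directed-simplex node participation,
# enrichment, hexagonal binning, meso-scale graphs and rich clubs.

#' Hexagonal binning of flat-space locations
#'
#' Tiles the plane with regular hexagons of the given flat-to-flat
#' diameter (which equals the centre-to-centre pitch of adjacent
#' hexagons) and assigns each point to the hexagon whose centre is
#' nearest, via exact cube-coordinate rounding of the axial hex lattice.
#'
#' @param x,y Flat coordinates (um).
#' @param diameter Flat-to-flat hexagon diameter (um).
#' @return List with `bin` (integer assignment, densely renumbered in
#'   order of first appearance sorted by axial index), `centers` (data
#'   frame `bin`, `cx`, `cy`) and `diameter`.
#' @export
hex_bin <- function(x, y, diameter) {
  stopifnot(length(x) == length(y), diameter > 0)
  size <- diameter / sqrt(3) # circumradius for pointy-top hexagons
  # axial coordinates (pointy-top): x = size*sqrt(3)*(q + r/2), y = size*1.5*r
  qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / size
  rf <- (2 / 3 * y) / size
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_y <- !fix_x & dy > dz
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  ry[fix_y] <- -rx[fix_y] - rz[fix_y]
  rz <- -rx - ry # wherever z had largest error this recomputes it; exact otherwise
  q <- rx; r <- rz
  key <- paste(q, r)
  # deterministic dense numbering sorted by (q, r)
  uk <- unique(key[order(q, r)])
  bin <- match(key, uk)
  qs <- as.numeric(sub(" .*", "", uk))
  rs <- as.numeric(sub(".* ", "", uk))
  centers <- data.frame(bin = seq_along(uk),
                        cx = size * sqrt(3) * (qs + rs / 2),
                        cy = size * 1.5 * rs)
  list(bin = bin, centers = centers, diameter = diameter)
}

#' Directed-simplex node participation
#'
#' A directed k-simplex is a set of k+1 nodes that is all-to-all
#' connected in a feed-forward fashion (every subset has a unique source
#' and sink). The k-dimensional participation of a node is the number of
#' directed k-simplices containing it; for k = 1 this is the node's total
#' degree. Counting uses ordered-clique extension over sorted adjacency
#' intersections.
#'
#' @param edges Data frame with columns `from` and `to` (positive integer
#'   node ids), self-loops forbidden, duplicate edges ignored.
#' @param n_nodes Number of nodes (ids 1..n_nodes).
#' @param max_dim Highest dimension counted (>= 1).
#' @return Integer matrix (n_nodes x max_dim); column k holds Par_k.
#' @export
node_participation <- function(edges, n_nodes, max_dim = 3) {
  if (max_dim < 1) stop("max_dim must be at least 1")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  m <- .count_simplices(as.integer(n_nodes), as.integer(edges$from),
                        as.integer(edges$to), as.integer(max_dim))
  colnames(m) <- paste0("dim", seq_len(max_dim))
  m
}

#' Participation-weighted mean of a node property
#'
#' Weighted average of a per-node property with weights given by node
#' participation in dimension k. An alternative printed convention with an
#' extra 1/N prefactor is available behind `per_node` for compatibility.
#'
#' @param values Numeric vector of the property per node.
#' @param participation Matrix from [node_participation()].
#' @param k Dimension (column) to weight by.
#' @param per_node If `TRUE`, divide additionally by the number of nodes
#'   (compatibility mode; not a weighted average).
#' @return Scalar weighted mean.
#' @export
weighted_mean_by_dimension <- function(values, participation, k,
                                       per_node = FALSE) {
  w <- participation[, k]
  tw <- sum(w)
  if (tw == 0) stop("total participation in dimension ", k, " is zero")
  res <- sum(values * w) / tw
  if (per_node) res <- res / length(values)
  res
}

#' Hypergeometric enrichment of a cell type in a top set
#'
#' Exact hypergeometric tail probabilities for the count of a given
#' m-type among the nodes with the highest node-participation values:
#' underexpression is P(Counts <= C_m) and overexpression is
#' P(Counts >= C_m) = 1 - F(C_m - 1).
#'
#' @param N_total Total number of neurons.
#' @param N_m Number of neurons of the m-type.
#' @param C_top Size of the top set.
#' @param C_m Number of m-type neurons in the top set.
#' @return List with `p_under` and `p_over`.
#' @export
hypergeom_enrichment <- function(N_total, N_m, C_top, C_m) {
  stopifnot(C_m <= C_top, N_m <= N_total, C_m <= N_m)
  p_under <- phyper(C_m, N_m, N_total - N_m, C_top)
  p_over <- 1 - phyper(C_m - 1, N_m, N_total - N_m, C_top)
  list(p_under = p_under, p_over = p_over)
}

#' Top-participation node set
#'
#' Nodes whose participation in dimension k lies in the highest 5\% of
#' values; ties at the cutoff are all included.
#'
#' @param participation Matrix from [node_participation()].
#' @param k Dimension.
#' @param top_frac Fraction (default 0.05).
#' @return Integer vector of node indices.
#' @export
top_participation_set <- function(participation, k, top_frac = 0.05) {
  v <- participation[, k]
  n_top <- max(1L, ceiling(top_frac * length(v)))
  cut <- sort(v, decreasing = TRUE)[n_top]
  which(v >= cut)
}

#' Meso-scale connectivity and correlation graph
#'
#' Assigns neurons to hexagonal subvolumes in flat space, counts synapses
#' within and between subvolumes (S, the adjacency matrix of the
#' meso-graph), and computes Pearson correlations of the subvolumes'
#' pooled 5 ms-binned spike-count series (F). Within-subvolume entries of
#' F use the separate series of the E and I populations.
#'
#' @param recording A `spike_recording`.
#' @param connectome The connectome (for neuron locations, classes and
#'   edges).
#' @param hex_diameter Subvolume diameter (um).
#' @param bin_ms Correlation time bin (ms; default 5).
#' @param t_start Discard spikes before this time (ms).
#' @return Object of class `meso_graph`: `S` (synapse counts), `F`
#'   (correlations), `centers`, `assignment` (per neuron), `hex_diameter`.
#' @export
meso_graph <- function(recording, connectome, hex_diameter, bin_ms = 5,
                       t_start = 0) {
  nn <- connectome$neurons
  hb <- hex_bin(nn$x, nn$y, hex_diameter)
  nb <- nrow(hb$centers)
  ed <- connectome$edges
  S <- matrix(0, nb, nb)
  if (nrow(ed) > 0) {
    b_pre <- hb$bin[match(ed$pre, nn$id)]
    b_post <- hb$bin[match(ed$post, nn$id)]
    agg <- stats::aggregate(ed$nsyn, list(pre = b_pre, post = b_post), sum)
    S[cbind(agg$pre, agg$post)] <- agg$x
  }
  edges_t <- seq(t_start, recording$duration, by = bin_ms)
  sp <- recording$spikes[recording$spikes$time_ms >= t_start, ]
  bin_of_neuron <- setNames(hb$bin, nn$id)
  series <- function(ids) {
    tv <- sp$time_ms[sp$neuron_id %in% ids]
    tabulate(findInterval(tv, edges_t), length(edges_t) - 1)
  }
  Fm <- matrix(NA_real_, nb, nb)
  pooled <- lapply(seq_len(nb), function(b) series(nn$id[hb$bin == b]))
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (i == j) {
        e_ids <- nn$id[hb$bin == i & nn$class == "E"]
        i_ids <- nn$id[hb$bin == i & nn$class == "I"]
        Fm[i, j] <- if (length(e_ids) && length(i_ids))
          suppressWarnings(cor(series(e_ids), series(i_ids))) else NA_real_
      } else if (j > i) {
        Fm[i, j] <- suppressWarnings(cor(pooled[[i]], pooled[[j]]))
        Fm[j, i] <- Fm[i, j]
      }
    }
  }
  structure(list(S = S, F = Fm, centers = hb$centers, assignment = hb$bin,
                 hex_diameter = hex_diameter, bin_ms = bin_ms),
            class = "meso_graph")
}

#' Estimate the correlation of mid-range inputs into a subvolume
#'
#' For subvolume i with input-count vector S_i, the outer product
#' P = S_i S_i^T counts pairs of inputs from every source pair; weighting
#' the correlation matrix F by P yields the distribution (and mean) of
#' the correlations of inputs into i.
#'
#' @param meso A [meso_graph()].
#' @param i Target subvolume index.
#' @return List with `mean` (pair-count-weighted mean input correlation)
#'   and `distribution` (data frame `source_a`, `source_b`, `weight`,
#'   `correlation`).
#' @export
input_correlation_estimate <- function(meso, i) {
  s_i <- meso$S[, i]
  P <- outer(s_i, s_i)
  rows <- which(P > 0 & is.finite(meso$F), arr.ind = TRUE)
  if (nrow(rows) == 0) stop("subvolume has no weighted inputs")
  w <- P[rows]
  r <- meso$F[rows]
  data.frame(source_a = rows[, 1], source_b = rows[, 2], weight = w,
             correlation = r) -> dist
  list(mean = sum(w * r) / sum(w), distribution = dist)
}

#' Rich-club membership at a synapse-count threshold
#'
#' Thresholds the meso-graph's synapse-count matrix, keeps edges at or
#' above the threshold, and reports connected components (in the
#' undirected sense) together with per-subvolume membership and
#' adjacency-to-member flags. A rich club appears as a single large
#' component while most subvolumes are isolated.
#'
#' @param S Synapse-count matrix (or a `meso_graph`).
#' @param threshold Synapse-count threshold.
#' @return List with `membership` (component id per subvolume, singletons
#'   included), `in_club` (belongs to a component with >= 2 members),
#'   `adjacent_to_club` (connected in S, at any strength, to a club
#'   member), `components`.
#' @export
rich_club <- function(S, threshold) {
  if (inherits(S, "meso_graph")) S <- S$S
  A <- (S >= threshold)
  diag(A) <- FALSE
  A <- A | t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  in_club <- comp$csize[comp$membership] >= 2
  anyS <- (S > 0) | (t(S) > 0)
  diag(anyS) <- FALSE
  adjacent <- as.logical(anyS %*% in_club > 0) & !in_club
  list(membership = comp$membership, in_club = in_club,
       adjacent_to_club = adjacent, components = comp)
}

#' Missing-synapse estimate from dendritic length
#'
#' Expected total excitatory synapse count from a fixed linear density
#' (1.1 synapses/um of dendrite) minus the synapses already present.
#'
#' @param dendritic_length_um Total dendritic length (um).
#' @param existing_count Synapses present in the model.
#' @param density Synapses per um (default 1.1).
#' @return Count (>= 0) with attribute `saturated` when the existing
#'   count already exceeds the estimate.
#' @export
missing_synapses <- function(dendritic_length_um, existing_count,
                             density = 1.1) {
  tot <- round(density * dendritic_length_um)
  structure(max(0, tot - existing_count),
            saturated = existing_count > tot)
}

#' Correlation of subvolume activity against distance
#'
#' @param meso A [meso_graph()].
#' @param n_breaks Number of distance bins.
#' @return Data frame `distance_um` (bin centre), `mean_r`, `n_pairs`.
#' @export
correlation_vs_distance <- function(meso, n_breaks = 10) {
  ctr <- meso$centers
  nb <- nrow(ctr)
  pairs <- which(upper.tri(meso$F), arr.ind = TRUE)
  d <- sqrt((ctr$cx[pairs[, 1]] - ctr$cx[pairs[, 2]])^2 +
              (ctr$cy[pairs[, 1]] - ctr$cy[pairs[, 2]])^2)
  r <- meso$F[pairs]
  ok <- is.finite(r)
  d <- d[ok]; r <- r[ok]
  brks <- seq(0, max(d) + 1e-9, length.out = n_breaks + 1)
  ix <- findInterval(d, brks, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(sort(unique(ix)), function(b)
    data.frame(distance_um = mean(brks[b + 0:1]), mean_r = mean(r[ix == b]),
               n_pairs = sum(ix == b))))
  rownames(out) <- NULL
  out
}
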