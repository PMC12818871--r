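# Simplex participation, enrichment, hex binning, meso graphs, rich club.

test_that("hexagonal binning partitions points onto the nearest centres", {
  hb0 <- hex_bin(c(0, 520, 260), c(0, 0, 450.3), diameter = 520)
  # three distinct neighbouring hexagons
  expect_equal(length(unique(hb0$bin)), 3)
  # points at hexagon centres stay there; 1 um displacement does not move
  ctr <- hb0$centers
  hb1 <- hex_bin(ctr$cx, ctr$cy, 520)
  hb2 <- hex_bin(ctr$cx + 1, ctr$cy, 520)
  expect_equal(hb1$bin, hb2$bin)
  # partition: every point gets exactly one bin
  with_seed(21, {
    x <- runif(500, 0, 2000); y <- runif(500, 0, 2000)
  })
  hb <- hex_bin(x, y, 400)
  expect_length(hb$bin, 500)
  expect_true(all(hb$bin >= 1 & hb$bin <= nrow(hb$centers)))
  # adjacent centres are exactly one pitch (= diameter) apart
  d <- as.matrix(dist(hb$centers[, c("cx", "cy")]))
  diag(d) <- Inf
  expect_lt(abs(min(d) - 400), 1e-9)
})

test_that("node participation matches closed forms on feed-forward cliques", {
  expect_error(node_participation(data.frame(from = 1, to = 2), 2, 0),
               "max_dim")
  # edgeless graph
  empty <- node_participation(data.frame(from = integer(0),
                                         to = integer(0)), 5, 3)
  expect_true(all(empty == 0))
  # complete feed-forward digraph on 4 nodes
  p4 <- node_participation(complete_ff(4), 4, 3)
  expect_equal(unname(p4[, 1]), rep(3, 4))       # total degree
  expect_equal(unname(p4[, 3]), rep(1, 4))       # each node in the single
  expect_equal(sum(p4[, 3]) / 4, 1)              # 3-simplex
  # Par_d(v) = choose(k - 1, d) for every node of a k-clique
  for (k in c(5, 7)) {
    pk <- node_participation(complete_ff(k), k, k - 1)
    for (d in seq_len(k - 1))
      expect_equal(unname(pk[, d]), rep(choose(k - 1, d), k))
  }
})

test_that("node participation equals brute-force enumeration on random digraphs", {
  for (s in 1:25) {
    n <- sample(5:10, 1)
    g <- random_digraph(n, p = runif(1, 0.2, 0.5), seed = 1000 + s)
    got <- node_participation(g, n, 4)
    want <- brute_participation(g, n, 4)
    expect_equal(unname(got), want, info = paste("graph seed", s))
  }
})

test_that("participation-weighted means satisfy the weighted-average identities", {
  g <- complete_ff(4)
  par <- node_participation(g, 4, 3)
  vals <- c(10, 10, 10, 10)
  for (k in 1:3)
    expect_equal(weighted_mean_by_dimension(vals, par, k), 10)
  # concentrated participation -> that node's value
  par1 <- matrix(0, 4, 1); par1[2, 1] <- 5
  expect_equal(weighted_mean_by_dimension(c(1, 7, 3, 4), par1, 1), 7)
  # hand-computed dot product
  v <- c(1, 2, 3, 4)
  expect_equal(weighted_mean_by_dimension(v, par, 2),
               sum(v * par[, 2]) / sum(par[, 2]))
  # printed-convention compatibility switch
  expect_equal(weighted_mean_by_dimension(v, par, 2, per_node = TRUE),
               sum(v * par[, 2]) / sum(par[, 2]) / 4)
  expect_error(weighted_mean_by_dimension(v, matrix(0, 4, 1), 1), "zero")
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  he <- hypergeom_enrichment(10, 5, 2, 2)
  expect_equal(he$p_over, choose(5, 2) / choose(10, 2))
  # full CDF
  expect_equal(hypergeom_enrichment(10, 5, 3, 3)$p_under, 1)
  # shared mass at C_m: p_under + p_over >= 1
  for (cm in 0:3) {
    he2 <- hypergeom_enrichment(12, 6, 3, cm)
    expect_gte(he2$p_under + he2$p_over, 1)
  }
  # top-5% set includes ties at the cutoff
  par <- matrix(c(rep(1, 95), rep(9, 5)), ncol = 1)
  expect_equal(top_participation_set(par, 1), 96:100)
  par_tie <- matrix(c(rep(1, 90), rep(9, 10)), ncol = 1)
  expect_equal(top_participation_set(par_tie, 1), 91:100)
})

meso_fixture <- function(seed = 5, correlated = FALSE) {
  # two spatially separated clusters of neurons with E/I classes
  nn <- data.frame(id = 1:40,
                   population = rep(c("L5_E", "L5_I"), 20),
                   class = rep(c("E", "I"), 20),
                   depth = 1000,
                   x = c(rep(100, 20), rep(600, 20)),
                   y = 100)
  edges <- data.frame(pre = c(1, 3, 5, 21), post = c(23, 25, 7, 9),
                      nsyn = c(4, 2, 1, 3), delay = 1, pathway = "E->E")
  con <- structure(list(neurons = nn, edges = edges,
                        pathway_params = default_pathway_params(),
                        populations = default_populations(1)),
                   class = "connectome")
  with_seed(seed, {
    if (correlated) {
      base <- sort(runif(300, 0, 30e3))
      spikes <- data.frame(neuron_id = rep(1:40, each = 300),
                           time_ms = rep(base, 40) +
                             rep(runif(40, 0, 1), each = 300))
    } else {
      spikes <- data.frame(neuron_id = rep(1:40, each = 150),
                           time_ms = runif(6000, 0, 30e3))
    }
  })
  rec <- structure(list(spikes = spikes[order(spikes$time_ms), ],
                        duration = 30e3,
                        population_index = setNames(nn$population, nn$id)),
                   class = "spike_recording")
  list(con = con, rec = rec)
}

test_that("meso graph counts synapses and correlations between subvolumes", {
  fx <- meso_fixture()
  mg <- meso_graph(fx$rec, fx$con, hex_diameter = 400)
  expect_equal(sum(mg$S), sum(fx$con$edges$nsyn))
  expect_equal(nrow(mg$S), 2)
  # cross-cluster count: neurons 1..20 are one hexagon, 21..40 the other
  b <- mg$assignment
  expect_equal(length(unique(b[1:20])), 1)
  expect_true(b[1] != b[21])
  cross <- sum(fx$con$edges$nsyn[b[fx$con$edges$pre] != b[fx$con$edges$post]])
  expect_equal(mg$S[b[1], b[21]] + mg$S[b[21], b[1]], cross)
  # independent activity: off-diagonal correlation near zero
  expect_lt(abs(mg$F[1, 2]), 0.1)
  # shared activity: high correlation
  fxc <- meso_fixture(correlated = TRUE)
  mgc <- meso_graph(fxc$rec, fxc$con, hex_diameter = 400)
  expect_gt(mgc$F[1, 2], 0.9)
  # single subvolume: S is 1x1 with the total count
  con1 <- fx$con
  con1$neurons$x <- 100
  mg1 <- meso_graph(fx$rec, con1, hex_diameter = 5000)
  expect_equal(dim(mg1$S), c(1L, 1L))
  expect_equal(mg1$S[1, 1], sum(fx$con$edges$nsyn))
})

test_that("input-correlation estimates are pair-count weighted", {
  # hand-constructed: sources 1 and 2 feed target 3 with counts 2 and 1
  S <- matrix(0, 3, 3)
  S[1, 3] <- 2; S[2, 3] <- 1
  Fm <- matrix(c(1, 0.5, NA, 0.5, 0.8, NA, NA, NA, NA), 3, 3)
  meso <- structure(list(S = S, F = Fm), class = "meso_graph")
  est <- input_correlation_estimate(meso, 3)
  # weights: (1,1)=4, (1,2)=(2,1)=2 each, (2,2)=1
  want <- (4 * 1 + 2 * 0.5 + 2 * 0.5 + 1 * 0.8) / 9
  expect_equal(est$mean, want)
  # perfectly correlated sources -> mean 1
  F1 <- matrix(1, 3, 3)
  expect_equal(input_correlation_estimate(
    structure(list(S = S, F = F1), class = "meso_graph"), 3)$mean, 1)
  # single source -> concentrated on its self-correlation entry
  S1 <- matrix(0, 3, 3); S1[2, 3] <- 5
  est1 <- input_correlation_estimate(
    structure(list(S = S1, F = Fm), class = "meso_graph"), 3)
  expect_equal(est1$mean, Fm[2, 2])
  expect_equal(nrow(est1$distribution), 1)
})

test_that("rich-club membership follows thresholded components", {
  S <- matrix(0, 5, 5)
  S[1, 2] <- 9e6; S[2, 3] <- 8.5e6; S[4, 5] <- 1e5
  rc <- rich_club(S, threshold = 8e6)
  expect_true(all(rc$in_club[1:3]))
  expect_false(any(rc$in_club[4:5]))
  expect_equal(rc$membership[1], rc$membership[2])
  expect_equal(rc$membership[2], rc$membership[3])
  # adjacency-to-member flags use any-strength connectivity
  S2 <- S; S2[3, 4] <- 10
  rc2 <- rich_club(S2, threshold = 8e6)
  expect_true(rc2$adjacent_to_club[4])
  # threshold above the maximum: all singletons
  rc3 <- rich_club(S, threshold = 1e9)
  expect_false(any(rc3$in_club))
  # threshold 0 keeps the underlying graph connected components
  rc4 <- rich_club(S2, threshold = 1)
  expect_equal(length(unique(rc4$membership[1:5])), 1)
  # raising the threshold never adds members
  for (th in c(1e5, 1e6, 8e6, 9e6)) {
    lo <- rich_club(S2, th)$in_club
    hi <- rich_club(S2, th * 1.5)$in_club
    expect_true(all(lo | !hi))
  }
})

test_that("missing-synapse estimation is a floored difference", {
  expect_equal(as.numeric(missing_synapses(5000, 2000)), 3500)
  sat <- missing_synapses(1000, 2000)
  expect_equal(as.numeric(sat), 0)
  expect_true(attr(sat, "saturated"))
  expect_equal(as.numeric(missing_synapses(5000, 0, density = 0)), 0)
})

test_that("correlation-distance profiles behave at the fixed points", {
  fxc <- meso_fixture(correlated = TRUE)
  mgc <- meso_graph(fxc$rec, fxc$con, hex_diameter = 400)
  cd <- correlation_vs_distance(mgc, n_breaks = 3)
  expect_true(all(cd$mean_r > 0.9)) # identical activity -> r near 1
  fx <- meso_fixture()
  mg <- meso_graph(fx$rec, fx$con, hex_diameter = 400)
  cd0 <- correlation_vs_distance(mg, n_breaks = 3)
  expect_true(all(abs(cd0$mean_r) < 0.15))
})
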