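# PSTHs, evoked metrics, criteria, ratios, correlations, rate statistics.

make_recording <- function(spikes, duration, pops) {
  structure(list(spikes = spikes[order(spikes$time_ms), ],
                 duration = duration, population_index = pops),
            class = "spike_recording")
}

poisson_recording <- function(n_neurons, rate, duration_ms, seed,
                              pop = "L5_E") {
  with_seed(seed, {
    k <- rpois(n_neurons, rate * duration_ms / 1000)
    spikes <- data.frame(
      neuron_id = rep(seq_len(n_neurons), k),
      time_ms = runif(sum(k), 0, duration_ms))
    make_recording(spikes, duration_ms,
                   setNames(rep(pop, n_neurons), seq_len(n_neurons)))
  })
}

test_that("psth recovers a homogeneous Poisson rate and conserves mass", {
  rec <- poisson_recording(100, 10, 10e3, seed = 1)
  ps <- psth(rec, "L5_E", bin_ms = 5, sigma_bins = 1)
  expect_lt(abs(mean(ps$rate) - 10), 3 * sqrt(10 / (100 * 10)) * 3)
  raw <- psth(rec, "L5_E", bin_ms = 5, sigma_bins = 0)
  expect_identical(raw$rate, raw$raw) # smoothing identity at sigma = 0
  # mass conservation: sum(raw) * bin = spikes / trials / neurons
  expect_equal(sum(raw$raw) * raw$bin_ms / 1000,
               nrow(rec$spikes) / (1 * 100), tolerance = 1e-10)
  expect_error(psth(rec, "L4_I"), "empty population")
})

test_that("baseline-max normalisation of a flat histogram is all zeros", {
  rec <- poisson_recording(50, 5, 5e3, seed = 2)
  ps <- psth(rec, "L5_E", bin_ms = 5, sigma_bins = 1,
             normalization = "baseline_max",
             onsets = 2500, window = c(-2000, 2000))
  expect_true(all(ps$normalized <= 1 + 1e-9))
  flat <- psth(make_recording(data.frame(neuron_id = 1,
                                         time_ms = seq(5, 995, by = 10)),
                              1000, c(`1` = "L5_E")),
               "L5_E", bin_ms = 50, sigma_bins = 0,
               normalization = "baseline_max",
               onsets = 500, window = c(-500, 500))
  expect_true(all(abs(flat$normalized) < 1e-9))
})

rect_psth <- function(base, peak, t0, t1, bin = 1) {
  tt <- seq(-200 + bin / 2, 400 - bin / 2, by = bin)
  v <- ifelse(tt >= t0 & tt < t1, peak, base)
  structure(list(time_ms = tt, rate = v, raw = v, baseline = base,
                 bin_ms = bin, sigma_bins = 0, n_neurons = 1, n_trials = 1,
                 normalization = "none"), class = "psth")
}

test_that("evoked metrics follow the step geometry and are scale invariant", {
  ps <- rect_psth(2, 10, 20, 120)
  m <- evoked_metrics(ps)
  expect_lt(abs(m$latency_ms - 20), 1.01)
  expect_lt(abs(m$decay50_ms - 120), 1.01)
  expect_lt(abs(m$decay25_ms - 120), 1.01)
  expect_equal(m$R_E, 5)
  expect_true(m$responsive)
  m2 <- evoked_metrics(rect_psth(4, 20, 20, 120))
  expect_equal(m2$latency_ms, m$latency_ms)
  expect_equal(m2$decay50_ms, m$decay50_ms)
  expect_equal(m2$R_E, m$R_E)
  # no response above baseline -> flagged
  m3 <- evoked_metrics(rect_psth(5, 5, 20, 120))
  expect_false(m3$responsive)
})

test_that("criteria check applies the latency/decay/secondary-rise rules", {
  pops <- c("L23_E", "L4_E", "L1_I")
  mk <- function(lat) {
    ps <- rect_psth(1, 10, lat, lat + 60)
    list(metrics = evoked_metrics(ps), psth = ps)
  }
  model <- lapply(c(20, 25, 15), mk)
  names(model) <- pops
  ref <- list(L23_E = list(latency_ms = 20, decay50_ms = 80, decay25_ms = 80),
              L4_E = list(latency_ms = 20, decay50_ms = 85, decay25_ms = 85))
  res <- criteria_check(lapply(model, `[[`, "metrics"), ref,
                        lapply(model, `[[`, "psth"))
  expect_true(res$pass["latency", "L23_E"])
  expect_true(res$pass["latency", "L4_E"]) # lag 5 <= 10 ms
  expect_false("L1_I" %in% colnames(res$pass)) # excluded
  # a 15 ms latency excess fails that flag and the overall result
  model_bad <- model
  model_bad$L4_E <- mk(36)
  res_bad <- criteria_check(lapply(model_bad, `[[`, "metrics"), ref,
                            lapply(model_bad, `[[`, "psth"))
  expect_false(res_bad$pass["latency", "L4_E"])
  expect_false(res_bad$overall)
  # a late bump 40% above baseline fails the secondary-rise rule
  ps_bump <- rect_psth(1, 10, 20, 60)
  ps_bump$rate[ps_bump$time_ms > 80 & ps_bump$time_ms < 90] <-
    1 + 0.40 * 9
  model_bump <- model
  model_bump$L23_E <- list(metrics = evoked_metrics(ps_bump),
                           psth = ps_bump)
  res_bump <- criteria_check(lapply(model_bump, `[[`, "metrics"), ref,
                             lapply(model_bump, `[[`, "psth"))
  expect_false(res_bump$pass["secondary_rise", "L23_E"])
  expect_error(criteria_check(lapply(model, `[[`, "metrics"),
                              ref["L23_E"], lapply(model, `[[`, "psth")),
               "missing reference")
})

test_that("connected/unconnected ratio handles identities and edge cases", {
  a <- c(L5_E = 2, L5_I = 4)
  expect_equal(as.numeric(rcu_ratio(a, a)), c(1, 1))
  expect_equal(as.numeric(rcu_ratio(2 * a, a)), c(2, 2))
  r <- rcu_ratio(c(x = 0, y = 1), c(x = 0, y = 0))
  expect_true(is.nan(r[["x"]]))
  expect_equal(r[["y"]], Inf)
  expect_true(all(attr(r, "undefined")))
})

test_that("E-I histogram correlation has the expected fixed points", {
  tpl <- data.frame(neuron_id = 1L, time_ms = sort(runif(400, 0, 5000)))
  pops <- c(`1` = "L5_E", `2` = "L5_I")
  # I spikes an exact copy of E -> r = 1
  cp <- rbind(tpl, transform(tpl, neuron_id = 2L))
  expect_gt(ei_correlation(make_recording(cp, 5000, pops))[["overall"]],
            0.999)
  # anti-phase square waves -> strongly negative
  te <- unlist(lapply(seq(0, 4900, by = 100), function(o)
    if ((o / 100) %% 2 == 0) o + runif(30, 0, 100)))
  ti <- unlist(lapply(seq(0, 4900, by = 100), function(o)
    if ((o / 100) %% 2 == 1) o + runif(30, 0, 100)))
  anti <- rbind(data.frame(neuron_id = 1L, time_ms = te),
                data.frame(neuron_id = 2L, time_ms = ti))
  expect_lt(ei_correlation(make_recording(anti, 5000, pops))[["overall"]],
            -0.5)
  # independent Poisson populations -> r near 0
  with_seed(31, {
    ind <- rbind(data.frame(neuron_id = 1L,
                            time_ms = runif(2000, 0, 60e3)),
                 data.frame(neuron_id = 2L,
                            time_ms = runif(2000, 0, 60e3)))
  })
  r0 <- ei_correlation(make_recording(ind, 60e3, pops))[["overall"]]
  expect_lt(abs(r0), 0.05)
})

test_that("rate statistics recover lognormal parameters and sparsity", {
  n <- 1e4
  with_seed(17, {
    rates <- rlnorm(n, meanlog = log(2), sdlog = 0.5)
    k <- rpois(n, rates * 100) # 100 s recording
    spikes <- data.frame(neuron_id = rep(seq_len(n), k),
                         time_ms = runif(sum(k), 0, 100e3))
  })
  rec <- make_recording(spikes, 100e3,
                        setNames(rep("L5_E", n), seq_len(n)))
  st <- rate_distribution_stats(rec)
  expect_lt(abs(st$lognorm_mu - log(2)), 0.05 * abs(log(2)) + 0.02)
  expect_lt(abs(st$lognorm_sigma - 0.5), 0.05 * 0.5)
  # half the neurons silent -> sparsity exactly 0.5
  half <- make_recording(
    data.frame(neuron_id = rep(1:50, each = 3),
               time_ms = runif(150, 0, 1000)),
    1000, setNames(rep("L5_E", 100), 1:100))
  expect_equal(rate_distribution_stats(half)$sparsity, 0.5)
  # identical rates -> degenerate sd
  same <- make_recording(
    data.frame(neuron_id = rep(1:20, each = 5),
               time_ms = runif(100, 0, 1000)),
    1000, setNames(rep("L5_E", 20), 1:20))
  expect_lt(rate_distribution_stats(same)$lognorm_sigma, 1e-6)
})

test_that("layer 2/3 cell selection applies its three filters", {
  # construct voltage traces: cells 1-2 have a fast rise, cell 3 is slow
  tax <- seq(0, 1000, by = 1)
  mkv <- function(slope) {
    v <- rep(-70, length(tax))
    rise <- tax >= 500 & tax <= 520
    v[rise] <- -70 + slope * (tax[rise] - 500)
    v[tax > 520] <- v[sum(rise)]
    v
  }
  volts <- cbind(`1` = mkv(2), `2` = mkv(2), `3` = mkv(0.5))
  attr(volts, "time_ms") <- tax
  ctrl <- make_recording(data.frame(neuron_id = 2L, time_ms = 510),
                         1000, setNames(rep("L23_E", 3), 1:3))
  ctrl$voltages <- volts
  sel <- select_l23_cells(ctrl, NULL, candidate_ids = 1:3,
                          innervated_ids = c(1, 2, 3),
                          stim_window = c(500, 700))
  expect_equal(sel, 1L) # 2 spiked, 3 too slow
  sel2 <- select_l23_cells(ctrl, NULL, candidate_ids = 1:3,
                           innervated_ids = c(2, 3),
                           stim_window = c(500, 700))
  expect_length(sel2, 0) # 1 not innervated
})
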