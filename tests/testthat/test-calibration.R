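# chi/phi mappings and the compensation, PSP and mPSC calibration loops.

test_that("phi fitting recovers exponential coefficients exactly", {
  u <- 0:4
  samples <- data.frame(population = "L5_E", U_FR = u,
                        C_FR = 2 * exp(0.5 * u) - 1)
  phi <- fit_phi(samples)
  f <- phi$fits$L5_E
  expect_lt(abs(f$alpha - 2), 1e-6)
  expect_lt(abs(f$beta - 0.5), 1e-6)
  expect_lt(abs(f$kappa + 1), 1e-6)
  expect_false(f$linear)
  # collinear points fall back to a flagged linear fit
  lin <- fit_phi(data.frame(population = "L5_E", U_FR = u,
                            C_FR = 3 * u + 2))
  expect_true(lin$fits$L5_E$linear || abs(lin$fits$L5_E$beta) < 0.05)
  expect_error(fit_phi(data.frame(population = "x", U_FR = c(1, 2),
                                  C_FR = c(1, 2))), "3 distinct")
  expect_error(fit_phi(data.frame(population = "x", U_FR = c(1, 2, NaN),
                                  C_FR = c(1, 2, 3))), "non-finite")
})

test_that("noisy phi fits recover beta within 10% on average", {
  u <- seq(0, 4, length.out = 8)
  ok <- 0
  for (s in 1:100) {
    with_seed(s, {
      samples <- data.frame(population = "L5_E", U_FR = u,
                            C_FR = 2 * exp(0.5 * u) - 1 +
                              rnorm(length(u), sd = 0.05))
    })
    f <- fit_phi(samples)$fits$L5_E
    if (!f$linear && abs(f$beta - 0.5) / 0.5 < 0.10) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.9)
})

test_that("phi inversion satisfies its identities", {
  phi <- fit_phi(data.frame(population = "L5_E", U_FR = 0:4,
                            C_FR = 2 * exp(0.5 * (0:4)) - 1))
  inv <- invert_phi(phi, c(L5_E = 2 * exp(1) - 1))
  expect_lt(abs(inv$U_FR[["L5_E"]] - 2), 1e-6)
  # target = alpha + kappa -> U_FR = 0
  inv0 <- invert_phi(phi, c(L5_E = phi$fits$L5_E$alpha +
                              phi$fits$L5_E$kappa))
  expect_lt(abs(inv0$U_FR[["L5_E"]]), 1e-6)
  # identity initial mapping: U_FR = C_FR
  idp <- invert_phi(phi_identity(), setNames(seq(0.5, 4.5, by = 0.5),
                                             population_names()))
  expect_equal(unname(idp$U_FR), seq(0.5, 4.5, by = 0.5))
  # round trip phi(phi^-1(x)) = x
  x <- 3.7
  u <- invert_phi(phi, c(L5_E = x))$U_FR[["L5_E"]]
  expect_lt(abs(phi$fits$L5_E$alpha * exp(phi$fits$L5_E$beta * u) +
                  phi$fits$L5_E$kappa - x), 1e-9)
  # unreachable target flagged
  bad <- invert_phi(phi, c(L5_E = phi$fits$L5_E$kappa - 1))
  expect_true(bad$unreachable[["L5_E"]])
})

test_that("chi learning is monotone, invertible and calcium-independent", {
  con <- small_surrogate(30)
  cfg <- simulation_config(duration = 500, seed = 3)
  chi <- learn_chi(con, R_OU = 0.4, grid = seq(0, 50, by = 10),
                   sim_config = cfg)
  for (p in population_names()) {
    tb <- chi$tables[[p]]
    expect_true(all(diff(tb$rate) >= 0))
    r_pos <- tb$rate[tb$rate > 0]
    expect_true(all(diff(r_pos) > 0)) # strictly increasing where positive
  }
  # round trip: rate measured at OU_mu = 30 inverts to ~30
  r30 <- chi_rate(chi, setNames(rep(30, 9), population_names()))
  inv <- invert_chi(chi, r30)
  expect_lt(max(abs(inv$OU_mu - 30)), 1e-6)
  # rest-firing populations: a target below the rate at the lowest grid
  # point is pinned there and flagged
  tweaked <- chi
  tweaked$tables$L1_I$rate <- tweaked$tables$L1_I$rate + 2
  inv2 <- invert_chi(tweaked, c(setNames(rep(1, 9), population_names())))
  expect_true(inv2$unreachable[["L1_I"]])
  expect_equal(inv2$OU_mu[["L1_I"]], min(tweaked$tables$L1_I$OU_mu))
  # no synapses are active: the mapping is independent of calcium
  cfg_hi <- simulation_config(duration = 500, seed = 3, calcium_Cao = 1.1)
  chi_hi <- learn_chi(con, R_OU = 0.4, grid = seq(0, 50, by = 10),
                      sim_config = cfg_hi)
  for (p in population_names())
    expect_equal(chi$tables[[p]]$rate, chi_hi$tables[[p]]$rate)
})

test_that("bursting detection separates asynchronous from all-or-nothing", {
  with_seed(9, {
    async <- data.frame(neuron_id = sample(1:100, 3000, replace = TRUE),
                        time_ms = runif(3000, 0, 10e3))
    bursts <- data.frame(
      neuron_id = sample(1:100, 3000, replace = TRUE),
      time_ms = rep(seq(500, 9500, by = 1000), each = 300) +
        rnorm(3000, sd = 3))
  })
  mk <- function(sp) structure(
    list(spikes = sp[order(sp$time_ms), ], duration = 10e3,
         population_index = setNames(rep("L5_E", 100), 1:100)),
    class = "spike_recording")
  expect_false(detect_bursting(mk(async)))
  expect_true(detect_bursting(mk(bursts)))
  # sparse but asynchronous activity is not misclassified
  with_seed(10, {
    sparse <- data.frame(neuron_id = sample(1:100, 60, replace = TRUE),
                         time_ms = runif(60, 0, 10e3))
  })
  expect_false(detect_bursting(mk(sparse)))
})

test_that("PSP mean scales linearly in ghat and CV shrinks with the pool", {
  base <- tm_synapse_params(peak_conductance_ghat = 0.4,
                            release_prob_USE = 0.5, vesicle_pool_NRRP = 4,
                            conductance_ratio_ghat_ratio = 0,
                            spontaneous_rate = 0)
  m1 <- measure_psp(base, n_pairs = 30, n_reps = 12, inter_rep_ms = 400,
                    seed = 2)
  dbl <- base
  dbl$peak_conductance_ghat <- 0.8
  m2 <- measure_psp(dbl, n_pairs = 30, n_reps = 12, inter_rep_ms = 400,
                    seed = 2)
  expect_lt(abs(m2$mean / m1$mean - 2), 0.05 * 2)
  # NRRP 1 vs 10 at matched mean amplitude: CV strictly larger for NRRP 1
  uni <- tm_synapse_params(peak_conductance_ghat = 2.0,
                           release_prob_USE = 0.5, vesicle_pool_NRRP = 1,
                           conductance_ratio_ghat_ratio = 0,
                           spontaneous_rate = 0)
  multi <- tm_synapse_params(peak_conductance_ghat = 0.2,
                             release_prob_USE = 0.5, vesicle_pool_NRRP = 10,
                             conductance_ratio_ghat_ratio = 0,
                             spontaneous_rate = 0)
  cv1 <- measure_psp(uni, n_pairs = 30, n_reps = 15, inter_rep_ms = 400,
                     seed = 3)$cv
  cv10 <- measure_psp(multi, n_pairs = 30, n_reps = 15, inter_rep_ms = 400,
                      seed = 3)$cv
  expect_gt(cv1, cv10)
})

test_that("PSP calibration is a fixed point at the current output", {
  path <- tm_synapse_params(peak_conductance_ghat = 0.5,
                            release_prob_USE = 0.5, vesicle_pool_NRRP = 3,
                            conductance_ratio_ghat_ratio = 0,
                            spontaneous_rate = 0)
  m <- measure_psp(path, n_pairs = 25, n_reps = 12, inter_rep_ms = 400,
                   seed = 7)
  cal <- calibrate_synapse_psp(path, target_mean = m$mean,
                               target_cv = m$cv, n_pairs = 25, n_reps = 12,
                               inter_rep_ms = 400, seed = 7)
  expect_equal(cal$iterations, 1)
  expect_equal(cal$ghat, 0.5)
  expect_equal(cal$NRRP, 3L)
})

test_that("mPSC calibration interpolates the logarithmic frequency fit", {
  # single synapse with an ideal detector: frequency equals the rate
  one <- calibrate_mpsc(1, target_mpsc_freq = 0.5,
                        candidate_rates = c(0.1, 0.3, 0.5, 1, 2),
                        duration_s = 400, detect_window_ms = 0, seed = 1)
  f_at <- one$table$mpsc_freq[one$table$rate == 0.5]
  expect_lt(abs(f_at - 0.5) / 0.5, 3 * sqrt(0.5 * 400) / (0.5 * 400))
  # many synapses: superposition is monotone and ~ n * rate less losses
  many <- calibrate_mpsc(100, target_mpsc_freq = 50,
                         candidate_rates = c(0.1, 0.25, 0.5, 1, 2),
                         duration_s = 60, seed = 2)
  expect_true(all(diff(many$table$mpsc_freq) > 0))
  expect_true(all(many$table$mpsc_freq <=
                    100 * many$table$rate * 60 / 60 + 1e-9))
  # the logarithmic fit inverts exactly on noise-free logarithmic data
  lg <- cortexsim:::.fit_log_interp(c(0.1, 0.3, 1, 3, 10),
                                    2 * log(c(0.1, 0.3, 1, 3, 10)) + 0.1,
                                    target = 2 * log(0.7) + 0.1)
  expect_lt(abs(lg$rate - 0.7) / 0.7, 0.01)
  # inversion identity: the fitted curve passes through the returned rate
  target <- many$table$mpsc_freq[3]
  back <- calibrate_mpsc(100, target, c(0.1, 0.25, 0.5, 1, 2),
                         duration_s = 60, seed = 2)
  pred <- back$fit[["a"]] * log(back$spontaneous_rate) + back$fit[["b"]]
  expect_lt(abs(pred - target), 1e-9)
  expect_warning(
    calibrate_mpsc(10, 1e4, c(0.1, 0.5, 1), duration_s = 20, seed = 3),
    "extrapolating")
})

test_that("compensation calibration contracts and recovers known injections", {
  # small fixture: 9 x 40 neurons, 4 levels, short simulations
  con <- small_surrogate(40, seed = 2)
  gin <- population_input_conductance(con)
  cfgf <- function(duration, seed)
    simulation_config(duration = duration, calcium_Cao = 1.05, seed = seed)
  chi <- learn_chi(con, R_OU = 0.4, grid = seq(0, 50, by = 5),
                   sim_config = simulation_config(duration = 800, seed = 21))
  # ground truth: forward-simulate a known OU_mu table, use the measured
  # rates as the reference vector
  mu_true <- setNames(seq(26, 34, length.out = 9), population_names())
  tab <- ou_injection_table(mu_true, R_OU = 0.4)
  ouv <- cortexsim:::.ou_vectors(con, tab, gin)
  rec <- simulate_network(con, cfgf(6000, 77), ou_g0 = ouv$g0,
                          ou_sigma = ouv$sigma)
  v_true <- population_rates(rec, t_start = 500)
  expect_true(all(v_true > 0))
  cal <- calibrate_compensation(con, meta_params(1.05, 0.4), v_true, chi,
                                n_levels = 4, max_iter = 6, tol = 0.25,
                                sim_duration = 3000, transient = 500,
                                seed = 5, sim_config_fn = cfgf)
  top <- cal$tables[[length(cal$tables)]]
  mu_rec <- vapply(top$params, function(p) p$OU_mu, numeric(1))
  expect_lt(max(abs(mu_rec - mu_true) / mu_true), 0.10)
  # contraction in practice: per-iteration worst distance does not increase
  # after the second iteration (up to measurement noise)
  worst <- tapply(cal$log$distance, cal$log$iteration, max)
  if (length(worst) > 2) {
    for (k in 3:length(worst))
      expect_lte(worst[k], worst[k - 1] + 0.3)
    expect_lte(worst[length(worst)], worst[2] + 0.1)
  }
  # compensation is population-specific when G_in and in-degree differ
  expect_gt(diff(range(mu_rec)), 1)
})
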