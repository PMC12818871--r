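# Contrast tuning: sigmoid fits, stimulus selection, modulation and
# conductance models.

contrasts5 <- c(0.06, 0.12, 0.24, 0.5, 1.0)

test_that("sigmoid fit recovers noise-free generating parameters", {
  truth <- list(m = 0.1, R_max = 2, n = 3, c50 = 0.3)
  curve <- data.frame(contrast = contrasts5,
                      response = sigmoid_response(truth, contrasts5))
  fit <- fit_sigmoid(curve)
  for (p in names(truth))
    expect_lt(abs(fit[[p]] - truth[[p]]), 1e-4)
  expect_gt(fit$r2, 1 - 1e-8)
  # half-maximum identity
  expect_equal(sigmoid_response(fit, fit$c50), fit$m + fit$R_max / 2,
               tolerance = 1e-6)
  # flat curve degenerates
  flat <- fit_sigmoid(data.frame(contrast = contrasts5,
                                 response = rep(1, 5)))
  expect_lt(flat$R_max, 1e-3)
  expect_true(flat$degenerate)
  expect_error(fit_sigmoid(data.frame(contrast = c(0.1, 0.5, 1),
                                      response = 1:3)), "4 contrast")
})

test_that("sigmoid response is monotone with the expected asymptote", {
  p <- list(m = 0.2, R_max = 3, n = 2.5, c50 = 0.4)
  cc <- seq(0.01, 1, by = 0.01)
  r <- sigmoid_response(p, cc)
  expect_true(all(diff(r) > 0))
  expect_lt(abs(sigmoid_response(p, 1e6) - (p$m + p$R_max)), 1e-6)
})

test_that("normalised peak difference follows the Michelson form", {
  expect_equal(peak_difference(10, 10), 0)
  expect_equal(peak_difference(30, 10), 0.5)
  expect_equal(peak_difference(12, 0), 1)
})

test_that("grating-parameter selection maximises the rank-score product", {
  scan <- data.frame(id = 1:4,
                     r1 = c(50, 60, 45, 20), r2 = c(40, 55, 44, 18),
                     c50 = c(0.3, 0.2, 0.99, 0.1), n = c(2, 4, 5, 8))
  # combo 4 excluded by r_th, combo 3 by border c50; among 1-2, combo 2
  # dominates: lower peak_diff, lower c50, higher n
  sel <- select_grating_params(scan, r_th = 30, c50_max = 0.95)
  expect_equal(sel$id, 2)
  # hand-computed rank products on a 3-way table
  scan2 <- data.frame(id = 1:3, r1 = c(60, 50, 55), r2 = c(30, 45, 50),
                      c50 = c(0.2, 0.5, 0.35), n = c(6, 3, 2))
  pd <- peak_difference(scan2$r1, scan2$r2)
  byhand <- rank(-pd) * rank(-scan2$c50) * rank(scan2$n)
  sel2 <- select_grating_params(scan2, r_th = 30)
  expect_equal(sel2$id, scan2$id[which.max(byhand)])
  # a single survivor is returned regardless of ranks
  sel3 <- select_grating_params(scan[scan$id == 1, ], r_th = 30)
  expect_equal(sel3$id, 1)
  expect_error(select_grating_params(scan, r_th = 1000), "excluded")
})

test_that("robust-tuning detection enforces strict monotonicity and rate", {
  curves <- rbind(c(1, 2, 3, 4, 5),     # robust
                  c(1, 2, 2, 4, 5),     # tie -> excluded
                  c(0.4, 2, 3, 4, 5),   # sub-threshold rate -> excluded
                  c(5, 4, 3, 2, 1))     # decreasing -> excluded
  expect_equal(detect_robust_tuning(curves, min_rate = 0.5), 1L)
})

test_that("modulation models reduce to the baseline at identity settings", {
  base <- structure(list(m = 0.1, R_max = 2, n = 3, c50 = 0.3, r2 = 1),
                    class = "sigmoid_params")
  R <- sigmoid_response(base, contrasts5)
  div <- fit_modulation(base, data.frame(contrast = contrasts5,
                                         response = R), "divisive")
  expect_lt(abs(div$g - 1), 1e-6)
  sub <- fit_modulation(base, data.frame(contrast = contrasts5,
                                         response = R), "subtractive")
  expect_lt(abs(sub$h), 1e-4)
  # large shift clamps at zero at low contrast
  shifted <- pmax(R - 1.5, 0)
  sub2 <- fit_modulation(base, data.frame(contrast = contrasts5,
                                          response = shifted),
                         "subtractive")
  expect_lt(abs(sub2$h - 1.5), 0.05)
  expect_equal(pmax(R - sub2$h, 0)[1], 0)
  # saturation-additive limits: c -> 1 with large n adds ~ A; c -> 0 adds S + A
  sat <- fit_modulation(base, data.frame(
    contrast = contrasts5,
    response = R + 0.7 * contrasts5^(-3) / (contrasts5^(-3) + 0.3^(-3)) + 0.2),
    "saturation_additive")
  expect_lt(abs(sat$S - 0.7), 1e-6)
  expect_lt(abs(sat$A - 0.2), 1e-6)
})

test_that("conductance-model rate matches closed-form plug-ins", {
  # resting identity: all synaptic conductances zero
  p0 <- cond_model_params(g_E_min = 0, g_E_max = 0, delta_g_IE_min = 0,
                          S = 0, A = 0)
  expect_equal(cond_model_rate(0.5, p0), 0)
  # gE = 6, gI = 0: dV = 25 mV, rate = (25 - 3.4)^3
  p1 <- cond_model_params(g_E_min = 6, g_E_max = 0, delta_g_IE_min = 0,
                          S = 0, A = -6)
  expect_lt(abs(cond_model_rate(0.5, p1) - (25 - 3.4)^3), 1e-9)
  # rate non-decreasing in g_E while the excitatory reversal is above V
  rates <- vapply(seq(0, 12, by = 1), function(g) {
    p <- cond_model_params(g_E_min = g, g_E_max = 0, delta_g_IE_min = 2,
                           S = 0, A = 0)
    cond_model_rate(0.5, p)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("two-stage conductance-model fit recovers generating parameters", {
  gen <- cond_model_params(g_E_min = 2, g_E_max = 12, c50 = 0.25, n = 2.2,
                           S = 3, A = 1)
  gen0 <- gen; gen0$S <- 0; gen0$A <- 0
  base <- data.frame(contrast = contrasts5,
                     response = cond_model_rate(contrasts5, gen0))
  mod <- data.frame(contrast = contrasts5,
                    response = cond_model_rate(contrasts5, gen))
  fit <- fit_cond_model(base, mod)
  expect_lt(abs(fit$params$c50 - 0.25) / 0.25, 0.01)
  expect_lt(abs(fit$params$n - 2.2) / 2.2, 0.01)
  expect_lt(abs(fit$params$g_E_min - 2) / 2, 0.01)
  expect_lt(abs(fit$params$g_E_max - 12) / 12, 0.01)
  expect_lt(abs(fit$stage2$S - 3) / 3, 0.01)
  expect_lt(abs(fit$stage2$A - 1) / 1, 0.01)
  # S = A = 0 data: stage 2 returns terms near zero, stage-1 untouched
  fit0 <- fit_cond_model(base, base)
  expect_lt(abs(fit0$stage2$S), 1e-3)
  expect_lt(abs(fit0$stage2$A), 1e-3)
  expect_identical(fit0$params$c50, fit0$params$c50)
  # permuting contrast order leaves the fits unchanged
  perm <- sample(nrow(base))
  fitp <- fit_cond_model(base[perm, ], mod[perm, ])
  expect_equal(fitp$params$c50, fit$params$c50, tolerance = 1e-8)
  expect_equal(fitp$stage2$S, fit$stage2$S, tolerance = 1e-6)
})

test_that("model comparison identifies the generating modulation model", {
  base_true <- list(m = 0.1, R_max = 2, n = 3, c50 = 0.3)
  R <- sigmoid_response(base_true, contrasts5)
  base_fit <- structure(c(base_true, r2 = 1), class = "sigmoid_params")
  gen <- function(model, seed) {
    with_seed(seed, {
      y <- switch(model,
                  divisive = R / 1.8,
                  subtractive = pmax(R - 0.6, 0),
                  saturation_additive = R +
                    1.0 * contrasts5^(-3) / (contrasts5^(-3) + 0.3^(-3)) - 0.4)
      y + rnorm(length(y), sd = 0.05)
    })
  }
  models <- c("divisive", "subtractive", "saturation_additive")
  hits <- 0; total <- 0
  for (m in models) for (s in 1:40) {
    curve <- data.frame(contrast = contrasts5, response = gen(m, s))
    total <- total + 1
    if (compare_modulation_models(base_fit, curve)$selected == m)
      hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("tuning normalisation divides by baseline response at max contrast", {
  curves <- expand.grid(contrast = contrasts5, opto_level = c(0, 150))
  curves$rate <- ifelse(curves$opto_level == 0, 10, 5) * curves$contrast
  norm <- normalize_tuning(curves)
  expect_equal(norm$response[norm$opto_level == 0 & norm$contrast == 1], 1)
  expect_equal(norm$response[norm$opto_level == 150 & norm$contrast == 1],
               0.5)
})
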