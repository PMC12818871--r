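# Contrast-tuning quantification and optogenetic-modulation models.

#' Fit a sigmoidal contrast-tuning function
#'
#' Least-squares fit of `R(c) = R_max * c^n / (c^n + c50^n) + m`, with a
#' multi-start over a coarse (n, c50) grid to avoid local minima. The
#' coefficient of determination (r^2) is reported as goodness of fit; a
#' flat curve yields R_max near 0 and a degenerate r^2, which is flagged.
#'
#' @param curve Data frame with columns `contrast` and `response`
#'   (normalised response); at least 4 contrast points.
#' @return Object of class `sigmoid_params`: `m`, `R_max`, `n`, `c50`,
#'   `r2`, `degenerate` flag.
#' @export
fit_sigmoid <- function(curve) {
  stopifnot(all(c("contrast", "response") %in% names(curve)))
  if (length(unique(curve$contrast)) < 4)
    stop("at least 4 contrast points are needed for a 4-parameter fit")
  span <- diff(range(curve$response))
  best <- NULL
  for (n0 in c(1, 2, 3, 5)) for (c0 in c(0.1, 0.2, 0.4, 0.7)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ R_max * contrast^n / (contrast^n + c50^n) + m,
        data = curve,
        start = list(m = min(curve$response), R_max = max(span, 1e-3),
                     n = n0, c50 = c0),
        lower = c(m = -Inf, R_max = 0, n = 1e-3, c50 = 1e-4),
        upper = c(m = Inf, R_max = Inf, n = 50, c50 = 1.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("sigmoid fit failed")
  cf <- coef(best$fit)
  tss <- sum((curve$response - mean(curve$response))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  structure(list(m = unname(cf["m"]), R_max = unname(cf["R_max"]),
                 n = unname(cf["n"]), c50 = unname(cf["c50"]), r2 = r2,
                 degenerate = tss <= 0 || cf["R_max"] < 1e-6),
            class = "sigmoid_params")
}

#' Evaluate a sigmoid tuning function
#'
#' @param params A `sigmoid_params` (or list with m, R_max, n, c50).
#' @param contrast Contrast values.
#' @return Response values.
#' @export
sigmoid_response <- function(params, contrast) {
  with(params, R_max * contrast^n / (contrast^n + c50^n) + m)
}

#' Normalised peak difference
#'
#' Michelson-type contrast of two peak rates: `(r1 - r2) / (r1 + r2)`.
#' Quantifies the attenuation of the response to the second grating cycle
#' relative to the first.
#'
#' @param r1,r2 First and second peak rates (Hz).
#' @return Unitless value in \[-1, 1\].
#' @export
peak_difference <- function(r1, r2) {
  (r1 - r2) / (r1 + r2)
}

#' Select stimulus parameters by rank-score product
#'
#' Given a scan of stimulus parameter combinations with their first/second
#' peak rates and sigmoid fits, excludes combinations with peak rates
#' below `r_th` or with border-case c50, ranks the remaining ones on
#' normalised peak difference (lower better), c50 (lower better) and
#' steepness n (higher better), and returns the combination with the
#' highest product of rank scores. Ties are broken deterministically in
#' favour of the lowest peak difference.
#'
#' @param scan Data frame with columns `r1`, `r2`, `c50`, `n` and any
#'   identifier columns.
#' @param r_th Peak-rate threshold (Hz; default 30).
#' @param c50_max Exclusion threshold for border-case c50 (default 0.95).
#' @return The selected row of `scan`, with added `peak_diff` and
#'   `rank_product` columns.
#' @export
select_grating_params <- function(scan, r_th = 30, c50_max = 0.95) {
  scan$peak_diff <- peak_difference(scan$r1, scan$r2)
  keep <- scan$r1 >= r_th & scan$r2 >= r_th & scan$c50 <= c50_max
  if (!any(keep)) stop("all parameter combinations excluded")
  sc <- scan[keep, , drop = FALSE]
  # rank scores: larger score is better
  score_low <- function(x) rank(-x, ties.method = "average")
  score_high <- function(x) rank(x, ties.method = "average")
  sc$rank_product <- score_low(sc$peak_diff) * score_low(sc$c50) *
    score_high(sc$n)
  sc <- sc[order(-sc$rank_product, sc$peak_diff), , drop = FALSE]
  sc[1, , drop = FALSE]
}

#' Detect neurons with robust contrast tuning
#'
#' A neuron is robustly tuned when it fires above a minimum rate under
#' every stimulus condition (so it could be detected by spike sorting)
#' and its tuning curve is strictly monotonically increasing in contrast.
#'
#' @param curves Matrix of mean rates (cells x contrasts, increasing
#'   contrast order), or data frame with `cell`, `contrast`, `rate`.
#' @param min_rate Minimum rate under all conditions (Hz; default 0.5).
#' @return Integer vector of row indices (or cell ids) passing both
#'   filters.
#' @export
detect_robust_tuning <- function(curves, min_rate = 0.5) {
  if (is.data.frame(curves)) {
    m <- do.call(rbind, lapply(split(curves, curves$cell), function(df)
      df$rate[order(df$contrast)]))
    ids <- as.integer(names(split(curves, curves$cell)))
  } else {
    m <- as.matrix(curves)
    ids <- seq_len(nrow(m))
  }
  ok <- apply(m, 1, function(r)
    all(r > min_rate) && all(diff(r) > 0))
  ids[ok]
}

#' Fit an optogenetic modulation model to a modulated tuning curve
#'
#' The baseline sigmoid parameters are kept fixed at their baseline-fit
#' values; only the modulation terms are free: `g` for the divisive
#' scaling model `R(c)/g`, `h` for the subtractive shifting model
#' `max(R(c) - h, 0)`, or `(S, A)` for the saturation-additive model
#' `R(c) + S c^-n / (c^-n + c50^-n) + A`.
#'
#' All three models are affine transforms of the baseline sigmoid shape,
#' with the saturation-additive family nesting the other two; raw r^2 is
#' therefore reported for comparability, and the parsimony-adjusted
#' `r2_adj` (adjusted for the number of free modulation terms) is the
#' quantity to compare when selecting between models.
#'
#' @param baseline A `sigmoid_params` from the unperturbed fit.
#' @param curve Modulated tuning curve (`contrast`, `response`).
#' @param model `"divisive"`, `"subtractive"` or `"saturation_additive"`.
#' @return List with the fitted term(s), `r2`, `r2_adj`, `n_terms` and
#'   `model`.
#' @export
fit_modulation <- function(baseline, curve,
                           model = c("divisive", "subtractive",
                                     "saturation_additive")) {
  model <- match.arg(model)
  if (is.null(baseline)) stop("baseline fit missing")
  R <- sigmoid_response(baseline, curve$contrast)
  y <- curve$response
  tss <- sum((y - mean(y))^2)
  nn <- length(y)
  r2_of <- function(pred) if (tss > 0) 1 - sum((y - pred)^2) / tss else NA_real_
  finish <- function(res, k) {
    res$n_terms <- k
    res$r2_adj <- if (is.na(res$r2)) NA_real_ else
      1 - (1 - res$r2) * (nn - 1) / (nn - 1 - k)
    res
  }
  if (model == "divisive") {
    f <- function(g) sum((y - R / g)^2)
    g <- optimize(f, c(1e-3, 1e3))$minimum
    # closed form refinement: minimise ||y - R/g||^2 over 1/g
    inv_g <- sum(y * R) / sum(R^2)
    if (f(1 / inv_g) < f(g)) g <- 1 / inv_g
    finish(list(model = model, g = g, r2 = r2_of(R / g)), 1)
  } else if (model == "subtractive") {
    # piecewise-quadratic in h with a flat plateau above max(R); a plain
    # golden search can stall on the plateau, so scan a grid first and
    # refine locally
    f <- function(h) sum((y - pmax(R - h, 0))^2)
    span <- max(abs(R), abs(y))
    grid <- seq(-2 * span, max(R), length.out = 401)
    h0 <- grid[which.min(vapply(grid, f, numeric(1)))]
    step <- diff(grid[1:2])
    h <- optimize(f, c(h0 - step, h0 + step))$minimum
    if (f(h0) < f(h)) h <- h0
    finish(list(model = model, h = h, r2 = r2_of(pmax(R - h, 0))), 1)
  } else {
    n <- baseline$n; c50 <- baseline$c50
    sat <- curve$contrast^(-n) / (curve$contrast^(-n) + c50^(-n))
    # linear in (S, A): least squares
    X <- cbind(S = sat, A = 1)
    cf <- solve(crossprod(X), crossprod(X, y - R))
    pred <- R + X %*% cf
    finish(list(model = model, S = unname(cf[1]), A = unname(cf[2]),
                r2 = r2_of(pred)), 2)
  }
}

#' Compare the three modulation models on one curve
#'
#' Fits the divisive, subtractive and saturation-additive models and
#' selects between them. Because the saturation-additive family nests the
#' other two (all three are affine transforms of the baseline sigmoid
#' shape), raw goodness of fit cannot identify a one-parameter truth;
#' selection therefore picks the better one-parameter model by residual
#' sum of squares and accepts the two-parameter saturation-additive model
#' only when it improves on it significantly (partial F-test at `alpha`;
#' conservative by default given the handful of contrast points).
#'
#' @param baseline A `sigmoid_params` baseline fit.
#' @param curve Modulated tuning curve (`contrast`, `response`).
#' @param alpha Significance level of the nested F-test (default 0.01).
#' @return List with `fits` (per model), `selected` (model name) and
#'   `f_p_value` of the nested comparison.
#' @export
compare_modulation_models <- function(baseline, curve, alpha = 0.01) {
  models <- c("divisive", "subtractive", "saturation_additive")
  fits <- lapply(models, function(m) fit_modulation(baseline, curve, m))
  names(fits) <- models
  tss <- sum((curve$response - mean(curve$response))^2)
  rss <- vapply(fits, function(f) (1 - f$r2) * tss, numeric(1))
  best1 <- models[1:2][which.min(rss[1:2])]
  n <- nrow(curve)
  df2 <- n - 2
  fstat <- (rss[best1] - rss["saturation_additive"]) /
    (rss["saturation_additive"] / df2)
  pval <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
  selected <- if (is.finite(pval) && pval < alpha)
    "saturation_additive" else best1
  list(fits = fits, selected = unname(selected), f_p_value = unname(pval))
}

#' Conductance-based model parameters for PC contrast responses
#'
#' Fixed biophysical constants of the two-stage population model of
#' pyramidal-cell contrast responses under interneuron photostimulation,
#' plus its free parameters.
#'
#' @param g_L Leak conductance (nS; 6).
#' @param R_L Leak reversal (mV; -50).
#' @param R_E_rev,R_I_rev Excitatory/inhibitory reversals (mV; 0, -65).
#' @param V_r Resting potential (mV; -50).
#' @param V_th_cubic Spike threshold of the cubic rectification (mV; 3.4).
#' @param g_E_min,g_E_max Excitatory conductance at low/high contrast (nS).
#' @param delta_g_IE_min Inhibitory conductance offset at low contrast
#'   (nS; 2).
#' @param c50,n Sigmoid parameters of the conductances.
#' @param S,A Saturation and additive photostimulation terms (nS).
#' @return Object of class `cond_model_params`.
#' @export
cond_model_params <- function(g_L = 6, R_L = -50, R_E_rev = 0,
                              R_I_rev = -65, V_r = -50, V_th_cubic = 3.4,
                              g_E_min = 1, g_E_max = 10,
                              delta_g_IE_min = 2, c50 = 0.2, n = 2,
                              S = 0, A = 0) {
  structure(list(g_L = g_L, R_L = R_L, R_E_rev = R_E_rev, R_I_rev = R_I_rev,
                 V_r = V_r, V_th_cubic = V_th_cubic, g_E_min = g_E_min,
                 g_E_max = g_E_max, delta_g_IE_min = delta_g_IE_min,
                 c50 = c50, n = n, S = S, A = A),
            class = "cond_model_params")
}

#' Conductance-based PC response rate at a given contrast
#'
#' Two-stage model: contrast sets the excitatory conductance through a
#' sigmoid, the inhibitory conductance adds a saturating
#' photostimulation term, the membrane potential follows from the
#' conductance balance, and the rate is the cubic rectification of the
#' potential above threshold (arbitrary units).
#'
#' @param contrast Contrast in \[0, 1\]; vectorised.
#' @param params A [cond_model_params()].
#' @return Rate (arbitrary units).
#' @export
cond_model_rate <- function(contrast, params) {
  p <- params
  gE <- p$g_E_max * contrast^p$n / (contrast^p$n + p$c50^p$n) + p$g_E_min
  sat <- contrast^(-p$n) / (contrast^(-p$n) + p$c50^(-p$n))
  sat[!is.finite(sat)] <- 1 # c = 0 limit of the saturating term
  gI <- gE + p$S * sat + p$delta_g_IE_min + p$A
  gtot <- p$g_L + gE + gI
  if (any(gtot == 0)) stop("total conductance is zero")
  dV <- (p$g_L * p$R_L + gE * p$R_E_rev + gI * p$R_I_rev) / gtot - p$V_r
  pmax(dV - p$V_th_cubic, 0)^3
}

#' Two-stage fit of the conductance-based PC model
#'
#' Stage 1: with S = A = 0, fit c50, g_E_min, g_E_max and n to the
#' baseline curve. Stage 2: keep those values bit-identical and fit S and
#' A to each photostimulation curve. Stage-1 failure aborts stage 2.
#'
#' @param baseline Data frame (`contrast`, `response`) of baseline PC
#'   responses.
#' @param modulated A data frame, or list of data frames, of responses
#'   under photostimulation.
#' @param constants A [cond_model_params()] supplying the fixed
#'   biophysical constants.
#' @return List with `params` (stage-1 [cond_model_params()]), `stage2`
#'   (data frame of S, A, r2 per modulated curve), `r2_baseline`.
#' @export
fit_cond_model <- function(baseline, modulated,
                           constants = cond_model_params()) {
  stopifnot(all(c("contrast", "response") %in% names(baseline)))
  if (is.data.frame(modulated)) modulated <- list(modulated)
  obj1 <- function(th) {
    p <- constants
    p$c50 <- th[1]; p$g_E_min <- th[2]; p$g_E_max <- th[3]; p$n <- th[4]
    p$S <- 0; p$A <- 0
    sum((baseline$response - cond_model_rate(baseline$contrast, p))^2)
  }
  best <- NULL
  for (c0 in c(0.1, 0.3, 0.6)) for (n0 in c(1, 2, 4)) {
    fit <- tryCatch(
      optim(c(c0, constants$g_E_min, constants$g_E_max, n0), obj1,
            method = "L-BFGS-B",
            lower = c(1e-3, 0, 1e-3, 0.1), upper = c(1.5, 100, 200, 20)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("stage-1 fit failed; stage 2 not attempted")
  p1 <- constants
  p1$c50 <- best$par[1]; p1$g_E_min <- best$par[2]
  p1$g_E_max <- best$par[3]; p1$n <- best$par[4]
  p1$S <- 0; p1$A <- 0
  tss <- sum((baseline$response - mean(baseline$response))^2)
  r2b <- if (tss > 0) 1 - best$value / tss else NA_real_
  stage2 <- do.call(rbind, lapply(seq_along(modulated), function(k) {
    mc <- modulated[[k]]
    obj2 <- function(th) {
      p <- p1; p$S <- th[1]; p$A <- th[2]
      sum((mc$response - cond_model_rate(mc$contrast, p))^2)
    }
    f2 <- optim(c(0, 0), obj2, method = "L-BFGS-B",
                lower = c(-100, -100), upper = c(100, 100))
    tss2 <- sum((mc$response - mean(mc$response))^2)
    data.frame(curve = k, S = f2$par[1], A = f2$par[2],
               r2 = if (tss2 > 0) 1 - f2$value / tss2 else NA_real_)
  }))
  list(params = p1, stage2 = stage2, r2_baseline = r2b)
}

#' Normalise tuning curves to the baseline maximal-contrast response
#'
#' Divides all mean responses (every optogenetic level) by the mean
#' baseline (no-photostimulation) firing rate at the highest contrast.
#'
#' @param curves Data frame `contrast`, `opto_level`, `rate`.
#' @param baseline_level Value of `opto_level` identifying baseline
#'   (default 0).
#' @return The data frame with an added `response` column.
#' @export
normalize_tuning <- function(curves, baseline_level = 0) {
  base <- curves[curves$opto_level == baseline_level, ]
  denom <- base$rate[which.max(base$contrast)]
  if (length(denom) == 0 || denom <= 0)
    stop("baseline response at maximal contrast unavailable")
  curves$response <- curves$rate / denom
  curves
}
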