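test_that("design matrix evaluates exp(-t/gamma) exactly", {
  g <- dt_grid(0.1, 100, 10)
  A <- build_design_matrix(c(0, 1, 2), g)
  expect_equal(A[1, ], rep(1, 10))
  A2 <- build_design_matrix(c(5), list(gammas = 5)$gammas)
  expect_equal(A2[1, 1], exp(-1), tolerance = 1e-15)
  # decreasing along lags at fixed gamma
  expect_true(all(diff(A[, 3]) < 0))
  expect_error(build_design_matrix(numeric(0), g), "empty")
})

test_that("regularized NNLS recovers one-hot targets and limiting cases", {
  g <- dt_grid(n_gamma = 60)
  lags <- 10^seq(log10(0.05), log10(50), length.out = 80)
  A <- build_design_matrix(lags, g)
  x0 <- numeric(60); x0[30] <- 1
  d <- solve_regularized(A, as.numeric(A %*% x0), alpha = 0)
  expect_gte(sum(d$weights[29:31]) / sum(d$weights), 0.95)
  expect_true(all(d$weights >= 0))
  # penalty-dominated limit flattens the solution
  d2 <- solve_regularized(A, as.numeric(A %*% x0), alpha = 1e4)
  expect_lt(d2$seminorm, 1e-4)
  # zero data gives zero weights
  d3 <- solve_regularized(A, numeric(80), alpha = 1)
  expect_equal(d3$weights, numeric(60))
})

test_that("L-curve corner balances fit and smoothness", {
  g <- dt_grid()
  lags_full <- seq(0.05, 50, by = 0.05)
  lags <- lags_full[unique(round(10^seq(0, log10(length(lags_full)),
                                        length.out = 150)))]
  A <- build_design_matrix(lags, g)
  G <- exp(-lags / g$gammas[54])  # on-grid single exponential
  sel <- select_alpha_lcurve(A, G)
  lc <- sel$lcurve
  ci <- attr(lc, "corner_index")
  expect_lt(sel$alpha, 0.1)
  expect_lt(lc$residual_norm[ci], 1e-3 * sqrt(sum(G^2)))
  # regularization path monotonicity (within solver tolerance)
  expect_true(all(diff(lc$residual_norm) > -1e-8))
  expect_true(all(diff(lc$seminorm) < 1e-8))
  # 1% noise moves the corner to larger alpha
  for (s in 1:3) {
    set.seed(s)
    seln <- select_alpha_lcurve(A, G + rnorm(length(G), sd = 0.01))
    expect_gt(seln$alpha, sel$alpha)
  }
  # degenerate flat curve falls back to the median alpha with a warning
  expect_warning(sel0 <- select_alpha_lcurve(A, numeric(nrow(A))),
                 "degenerate")
})

test_that("regularization path is monotone on random exponential mixtures", {
  g <- dt_grid(n_gamma = 60)
  lags <- 10^seq(log10(0.05), log10(50), length.out = 60)
  A <- build_design_matrix(lags, g)
  alphas <- 10^seq(-6, 2, length.out = 15)
  set.seed(31)
  for (i in 1:6) {
    k <- sample(1:3, 1)
    taus <- 10^runif(k, -0.5, 1.4)
    w <- runif(k); w <- w / sum(w)
    G <- colSums(w * exp(-outer(taus, lags, function(a, b) b / a))) +
      rnorm(length(lags), sd = 0.005)
    lc <- select_alpha_lcurve(A, G, alphas)$lcurve
    expect_true(all(diff(lc$residual_norm) > -1e-8))
    expect_true(all(diff(lc$seminorm) < 1e-8))
  }
})

test_that("single-exponential intensity AFC inverts to a peak at tau_c / 2", {
  lags <- seq(0.05, 50, by = 0.05)
  d <- invert_afc(list(lags = lags, values = exp(-2 * lags / 10)))
  pk <- find_dt_peaks(d)
  expect_equal(nrow(pk), 1)
  g <- d$gammas
  near5 <- which.min(abs(log(g) - log(5)))
  expect_lte(abs(which.min(abs(g - pk$gamma[1])) - near5), 1)
})

test_that("a three-component AFC yields three peaks at the component DTs", {
  taus <- c(0.165, 1.49, 24.6)
  lags <- seq(0.05, 50, by = 0.05)
  G <- colMeans(exp(-outer(taus, lags, function(a, b) b / a)))
  d <- invert_afc(list(lags = lags, values = G))
  pk <- find_dt_peaks(d)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$gamma, taus, tolerance = 0.15)
  # closed loop: reconstruction matches the fitted curve within 5%
  rec <- reconstruct_afc(d)
  expect_lt(sqrt(sum((rec - d$fit_values)^2) / sum(d$fit_values^2)), 0.05)
})

test_that("static and empty profiles yield empty distributions", {
  lags <- seq(0.05, 50, by = 0.05)
  d0 <- invert_afc(list(lags = lags, values = numeric(length(lags))))
  expect_true(d0$static)
  expect_equal(sum(d0$weights), 0)
  expect_equal(nrow(find_dt_peaks(d0)), 0)
  # below the static threshold at the first fitted lag
  d1 <- invert_afc(list(lags = lags, values = 0.05 * exp(-lags / 5)))
  expect_true(d1$static)
})

test_that("peak finding reports plateau, boundary and prominence correctly", {
  g <- 10^seq(-1, 2, length.out = 12)
  mk <- function(w) structure(list(gammas = g, weights = w),
                              class = "dt_distribution")
  # two clear peaks with a shallow saddle
  w <- c(0, 1, 0.2, 0, 0, 0.8, 0.1, 0, 0, 0, 0, 0)
  pk <- find_dt_peaks(mk(w))
  expect_equal(nrow(pk), 2)
  expect_equal(pk$prominence, c(1, 0.8))
  # plateau counts once
  wp <- c(0, 0.5, 0.5, 0.5, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(nrow(find_dt_peaks(mk(wp))), 1)
  # boundary maximum is eligible
  wb <- c(numeric(11), 1)
  expect_equal(find_dt_peaks(mk(wb))$gamma, g[12])
  # prominence filter drops shallow ripples riding on the main peak
  wr <- c(0, 1, 0.97, 0.99, 0.98, 0.995, 0, 0, 0, 0, 0, 0)
  expect_equal(nrow(find_dt_peaks(mk(wr), min_prominence_frac = 0.05)), 1)
})

test_that("reconstruct_afc is the weighted sum of exponentials", {
  g <- dt_grid(0.1, 100, 20)
  w <- numeric(20); w[7] <- 1
  d <- structure(list(gammas = g$gammas, weights = w, baseline = 0),
                 class = "dt_distribution")
  lags <- seq(0, 10, by = 0.5)
  expect_equal(reconstruct_afc(d, lags), exp(-lags / g$gammas[7]),
               tolerance = 1e-12)
  d0 <- structure(list(gammas = g$gammas, weights = numeric(20), baseline = 0),
                  class = "dt_distribution")
  expect_equal(reconstruct_afc(d0, lags), numeric(length(lags)))
})

test_that("noiseless mixtures of well-separated exponentials are recovered", {
  cfg <- contin_config(n_gamma = 80, alphas = 10^seq(-6, 2, length.out = 25))
  lags <- seq(0.05, 50, by = 0.05)
  gam <- dt_grid(cfg$gamma_min, cfg$gamma_max, cfg$n_gamma)$gammas
  bin_ratio <- gam[2] / gam[1]
  cases <- list(2, c(0.5, 8), c(0.3, 3, 30))
  for (taus in cases) {
    G <- colMeans(exp(-outer(taus, lags, function(a, b) b / a)))
    pk <- find_dt_peaks(invert_afc(list(lags = lags, values = G), cfg))
    expect_equal(nrow(pk), length(taus))
    for (tau in taus) {
      rel <- min(abs(log(pk$gamma) - log(tau)))
      expect_lt(rel, max(log(bin_ratio), log(1.15)))
    }
  }
  # with 1% noise, recovery within +-30%
  set.seed(17)
  taus <- c(0.5, 8)
  G <- colMeans(exp(-outer(taus, lags, function(a, b) b / a))) +
    rnorm(length(lags), sd = 0.01)
  pk <- find_dt_peaks(invert_afc(list(lags = lags, values = G), cfg))
  for (tau in taus) expect_lt(min(abs(log(pk$gamma) - log(tau))), log(1.3))
})

test_that("depth maps keep layers coherent and static rows empty", {
  spec <- phantom_spec(list(
      layer_spec("fast", c(0, 6), tau_c = 4, amplitude = 1),
      layer_spec("slow", c(6, 12), tau_c = 16, amplitude = 1),
      layer_spec("static", c(12, 16), tau_c = Inf, amplitude = 1)),
    n_depth = 16, n_time = 40000, noise_sigma = 0.02, seed = 5)
  ms <- simulate_mscan(spec)
  mr <- mean_removed_afc(ms, n_segments = 20, max_lag = 50)
  cfg <- contin_config(n_gamma = 60, alphas = 10^seq(-6, 2, length.out = 15))
  dm <- dt_depth_map(mr, cfg)
  expect_false(any(dm$failed))
  expect_true(all(dm$static[13:16]))
  expect_equal(rowSums(dm$weights[13:16, ]), numeric(4))
  dom <- apply(dm$weights[1:12, ], 1, function(w) dm$gammas[which.max(w)])
  # expected intensity DTs: tau_c / 2 = 2 and 8 ms; distinct coherent bands
  expect_true(all(dom[1:6] > 1 & dom[1:6] < 4))
  expect_true(all(dom[7:12] > 4 & dom[7:12] < 16))
  expect_lt(max(dom[1:6]) / min(dom[1:6]), 2.6)
})
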