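test_that("field traces respect the static limit and reject bad parameters", {
  set.seed(1)
  tr <- simulate_field_trace(Inf, 2, 0.05, 500)
  expect_true(all(tr == tr[1]))
  expect_equal(var(Mod(tr)^2), 0)
  expect_error(simulate_field_trace(-1, 1, 0.05, 10), "tau_c")
  expect_error(simulate_field_trace(10, 0, 0.05, 10), "amplitude")
  expect_error(simulate_field_trace(10, 1, 0, 10), "dt")
  expect_error(simulate_field_trace(10, 1, 0.05, 0), "n")
})

test_that("field autocorrelation of a simulated trace matches exp(-tau/tau_c)", {
  set.seed(7)
  tau_c <- 10; dt <- 0.05; n <- 200000
  tr <- simulate_field_trace(tau_c, 1, dt, n)
  for (tau in c(1, 5, 10)) {
    k <- round(tau / dt)
    g1 <- Mod(mean(Conj(tr[1:(n - k)]) * tr[(k + 1):n])) / mean(Mod(tr)^2)
    expect_lt(abs(g1 - exp(-tau / tau_c)), 0.05,
              label = sprintf("|g1| error at tau = %g ms", tau))
  }
})

test_that("intensity autocorrelation obeys the Siegert relation", {
  set.seed(11)
  tau_c <- 10; dt <- 0.05; n <- 200000
  I <- Mod(simulate_field_trace(tau_c, 1, dt, n))^2
  k <- round(5 / dt)
  G5 <- mean(I[1:(n - k)] * I[(k + 1):n]) / mean(I)^2
  expect_equal(G5, 1 + exp(-1), tolerance = 0.05)
})

test_that("Siegert conformance tightens as the trace grows", {
  dt <- 0.05; tau_c <- 5
  maxdev <- sapply(c(20000, 200000), function(n) {
    set.seed(3)
    I <- Mod(simulate_field_trace(tau_c, 1, dt, n))^2
    ks <- round(seq(0, 30, by = 1) / dt)
    emp <- sapply(ks, function(k)
      mean(I[1:(n - k)] * I[(k + 1):n]) / mean(I)^2)
    max(abs(emp - (1 + exp(-2 * ks * dt / tau_c))))
  })
  expect_lt(maxdev[2], maxdev[1])
})

test_that("M-scans honor layer structure, ground truth, and seed determinism", {
  spec <- phantom_spec(list(
      layer_spec("top", c(0, 4), tau_c = 5, amplitude = 1),
      layer_spec("bottom", c(4, 8), tau_c = Inf, amplitude = 1)),
    n_depth = 8, n_time = 3000, noise_sigma = 0, seed = 2)
  ms <- simulate_mscan(spec)
  v <- apply(Mod(ms$field)^2, 1, var)
  expect_true(all(outer(v[1:4], v[5:8], ">")))
  expect_equal(ms$truth$dynamic_mask, c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_equal(ms$truth$tau_c_map, c(rep(5, 4), rep(Inf, 4)))
  # static noiseless rows are constant in time
  expect_true(all(ms$field[5:8, ] == ms$field[5:8, 1]))
  expect_identical(simulate_mscan(spec)$field, ms$field)
  expect_error(phantom_spec(list(
    layer_spec("a", c(0, 5)), layer_spec("b", c(4, 8))), n_depth = 8),
    "overlap")
})

test_that("frame pairs decorrelate dynamic layers and only those", {
  # all static, no noise: identical frames
  sp0 <- phantom_spec(layer_spec("s", c(0, 10), tau_c = Inf),
                      n_depth = 10, n_alines = 50, noise_sigma = 0, seed = 1)
  p0 <- simulate_frame_pair(sp0)
  expect_identical(p0$frames[, , 1], p0$frames[, , 2])
  # tau_c = 10 ms over a 50 ms interval: rho = exp(-5), correlation ~ 0
  sp <- phantom_spec(layer_spec("d", c(0, 50), tau_c = 10),
                     n_depth = 50, n_alines = 2000, noise_sigma = 0, seed = 2)
  p <- simulate_frame_pair(sp)
  f1 <- p$frames[, , 1]; f2 <- p$frames[, , 2]
  cc <- Mod(sum(Conj(f1) * f2)) / sqrt(sum(Mod(f1)^2) * sum(Mod(f2)^2))
  expect_lt(abs(cc - exp(-5)), 0.05)
})

test_that("frame stacks extend the recursion with constant lag correlation", {
  # tau_c = 100 ms, 50 ms interval: rho = exp(-0.5)
  sp <- phantom_spec(layer_spec("d", c(0, 40), tau_c = 100),
                     n_depth = 40, n_alines = 1000, noise_sigma = 0, seed = 4)
  st <- simulate_frame_stack(sp, k = 6)
  rho <- exp(-sp$frame_interval / 100)
  for (j in 1:5) {
    f1 <- st$frames[, , j]; f2 <- st$frames[, , j + 1]
    cc <- Mod(sum(Conj(f1) * f2)) / sqrt(sum(Mod(f1)^2) * sum(Mod(f2)^2))
    expect_lt(abs(cc - rho), 0.05)
  }
})

test_that("fringe synthesis is Hermitian and inverts through reconstruction", {
  # zero field: constant fringe at the DC level
  fr0 <- synthesize_fringes(matrix(0i, 8, 3), dc_level = 5)
  expect_equal(fr0$fringes, matrix(5, nrow(fr0$fringes), 3))
  # single unit scatterer: pure cosine at its depth frequency
  f <- matrix(0i, 16, 1); f[4] <- 1
  fr <- synthesize_fringes(f, n_k = 64)
  k <- 0:63
  expect_equal(fr$fringes[, 1], 2 * cos(2 * pi * k * 4 / 64), tolerance = 1e-12)
  # round trip identity on random complex fields
  set.seed(5)
  F <- matrix(complex(real = rnorm(120), imaginary = rnorm(120)), 30, 4)
  rec <- reconstruct_ascan(synthesize_fringes(F, dc_level = 2))$field
  expect_lt(max(Mod(rec[1:30, ] - F)) / max(Mod(F)), 1e-9)
  expect_error(synthesize_fringes(F, n_k = 60), "aliasing")
})

test_that("phantom specs round-trip through JSON", {
  sp <- two_layer_spec()
  js <- phantom_spec_to_json(sp)
  sp2 <- phantom_spec_from_json(js)
  expect_equal(sp2, sp)
  expect_identical(simulate_frame_pair(sp2)$frames,
                   simulate_frame_pair(sp)$frames)
})
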