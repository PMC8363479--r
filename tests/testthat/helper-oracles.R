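# Brute-force reference implementations, kept deliberately independent of the
# package's FFT-based estimators.

# raw normalized intensity autocorrelation, direct double loop:
# per segment, G(tau) = mean_t[I(t) I(t+tau)] / mean(I)^2 over the available
# products; averaged over contiguous equal-length segments
brute_afc <- function(I, n_segments, K) {
  L <- length(I) %/% n_segments
  acc <- numeric(K + 1)
  for (s in seq_len(n_segments)) {
    seg <- I[((s - 1) * L + 1):(s * L)]
    m <- mean(seg)
    for (k in 0:K) {
      prods <- 0
      for (t in 1:(L - k)) prods <- prods + seg[t] * seg[t + k]
      acc[k + 1] <- acc[k + 1] + (prods / (L - k)) / m^2
    }
  }
  acc / n_segments
}

# mean-removed, tau = 0 normalized variant of the same estimator
brute_mean_removed_afc <- function(I, n_segments, K) {
  L <- length(I) %/% n_segments
  acc <- numeric(K + 1)
  for (s in seq_len(n_segments)) {
    seg <- I[((s - 1) * L + 1):(s * L)]
    seg <- seg - mean(seg)
    for (k in 0:K) {
      prods <- 0
      for (t in 1:(L - k)) prods <- prods + seg[t] * seg[t + k]
      acc[k + 1] <- acc[k + 1] + prods / (L - k)
    }
  }
  acc / acc[1]
}

# two-layer phantom used across segmentation / variance tests
two_layer_spec <- function(top_tau = 10, top_amp = 1, bottom_amp = 1,
                           n_depth = 120, n_alines = 400,
                           noise_sigma = 0.05, seed = 1) {
  phantom_spec(list(
    layer_spec("dynamic", c(20, 60), tau_c = top_tau, amplitude = top_amp),
    layer_spec("static", c(60, 100), tau_c = Inf, amplitude = bottom_amp)),
    n_depth = n_depth, n_alines = n_alines, n_time = 2000,
    noise_sigma = noise_sigma, seed = seed)
}

# signal-free rows of that phantom, for noise-floor estimation
two_layer_noise_rows <- function(spec) {
  amp <- rep(0, spec$n_depth)
  for (l in spec$layers) amp[(l$depth_range[1] + 1):l$depth_range[2]] <- l$amplitude
  which(amp == 0)
}
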