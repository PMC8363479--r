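# Linear (non-circular) autocorrelation sums s_tau = sum_t x[t] x[t+tau],
# tau = 0..K, via zero-padded FFT.
autocorr_sums <- function(x, K) {
  L <- length(x)
  nfft <- stats::nextn(L + K, 2)
  X <- stats::fft(c(x, numeric(nfft - L)))
  s <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / nfft
  s[seq_len(K + 1)]
}

as_intensity_matrix <- function(mscan, dt) {
  if (inherits(mscan, "complex_mscan")) {
    list(I = Mod(mscan$field)^2, dt = mscan$dt)
  } else if (is.complex(mscan)) {
    if (is.null(dt)) stop("compute_afc: dt must be given for a bare matrix")
    list(I = Mod(as.matrix(mscan))^2, dt = dt)
  } else {
    if (is.null(dt)) stop("compute_afc: dt must be given for a bare matrix")
    I <- if (is.matrix(mscan)) mscan else matrix(mscan, nrow = 1)
    if (any(I < 0)) stop("compute_afc: intensity input must be nonnegative")
    list(I = I, dt = dt)
  }
}

afc_lag_setup <- function(n_time, n_segments, max_lag, dt) {
  if (!(n_segments >= 1 && n_segments == round(n_segments)))
    stop("n_segments must be a positive integer")
  L <- n_time %/% n_segments  # trailing remainder discarded
  K <- floor(max_lag / dt + 1e-9)
  if (K + 1 > L)
    stop(sprintf("max_lag (%g ms) must be shorter than the segment duration (%g ms)",
                 max_lag, L * dt))
  list(L = L, K = K, lags = (0:K) * dt)
}

#' Depth-resolved intensity autocorrelation of an M-scan
#'
#' Computes, per depth, the normalized intensity autocorrelation
#' `G(tau) = <I(t) I(t+tau)> / <I(t)>^2` with segmented averaging: the time
#' trace is split into `n_segments` contiguous equal-length blocks (the
#' trailing remainder is discarded), `G` is estimated per block over lags
#' `0..max_lag` using the `L - tau/dt` available products (no wrap-around, no
#' zero padding) and the block's own mean in the denominator, and the reported
#' curve is the arithmetic mean of the block curves. For complex circular
#' Gaussian speckle the Siegert relation gives
#' `G(tau) = 1 + exp(-2 tau / tau_c)`.
#'
#' @param mscan A `complex_mscan` (from [simulate_mscan()]), a complex
#'   depth x time matrix, or a nonnegative intensity matrix (rows = depths).
#' @param n_segments Number of averaging segments (default 20).
#' @param max_lag Maximum lag in ms (default 50); must be shorter than one
#'   segment.
#' @param dt Sample interval in ms; taken from the `complex_mscan` when given.
#' @return Object of class `afc_map`: `lags` (ms, from 0), `values`
#'   (depth x lag matrix), `n_segments`, `dt`, `type = "raw"`, and `valid`
#'   (per-depth flag, `FALSE` where a segment had zero mean intensity; such
#'   rows are `NA`).
#' @export
compute_afc <- function(mscan, n_segments = 20L, max_lag = 50, dt = NULL) {
  inp <- as_intensity_matrix(mscan, dt)
  I <- inp$I; dt <- inp$dt
  su <- afc_lag_setup(ncol(I), n_segments, max_lag, dt)
  L <- su$L; K <- su$K
  vals <- matrix(NA_real_, nrow(I), K + 1)
  valid <- rep(TRUE, nrow(I))
  denom_counts <- L - 0:K
  for (z in seq_len(nrow(I))) {
    acc <- numeric(K + 1)
    for (s in seq_len(n_segments)) {
      seg <- I[z, ((s - 1) * L + 1):(s * L)]
      m <- mean(seg)
      if (m == 0) { valid[z] <- FALSE; break }
      acc <- acc + (autocorr_sums(seg, K) / denom_counts) / m^2
    }
    if (valid[z]) vals[z, ] <- acc / n_segments
  }
  structure(list(lags = su$lags, values = vals, n_segments = n_segments,
                 dt = dt, type = "raw", valid = valid),
            class = "afc_map")
}

#' Mean-removed, tau = 0 normalized autocorrelation
#'
#' As [compute_afc()], but the per-segment mean intensity is subtracted
#' before correlating (an autocovariance), and the segment-averaged curve is
#' divided by its value at `tau = 0`, so every dynamic profile starts at
#' exactly 1 and decays toward 0. Removing the mean keeps only the dynamic
#' part of the record: static tissue leaves just uncorrelated background
#' noise, a sharp peak at `tau = 0` with no tail. A depth with zero temporal
#' variance is flagged static and returned as 1 at `tau = 0` with an all-zero
#' tail by convention.
#'
#' @inheritParams compute_afc
#' @return An `afc_map` with `type = "mean_removed"` and a per-depth
#'   `static` flag.
#' @export
mean_removed_afc <- function(mscan, n_segments = 20L, max_lag = 50, dt = NULL) {
  inp <- as_intensity_matrix(mscan, dt)
  I <- inp$I; dt <- inp$dt
  su <- afc_lag_setup(ncol(I), n_segments, max_lag, dt)
  L <- su$L; K <- su$K
  vals <- matrix(NA_real_, nrow(I), K + 1)
  static <- rep(FALSE, nrow(I))
  denom_counts <- L - 0:K
  for (z in seq_len(nrow(I))) {
    acc <- numeric(K + 1)
    for (s in seq_len(n_segments)) {
      seg <- I[z, ((s - 1) * L + 1):(s * L)]
      acc <- acc + autocorr_sums(seg - mean(seg), K) / denom_counts
    }
    c0 <- acc[1]
    if (c0 <= 0) {
      static[z] <- TRUE
      vals[z, ] <- c(1, numeric(K))
    } else {
      vals[z, ] <- acc / c0
    }
  }
  structure(list(lags = su$lags, values = vals, n_segments = n_segments,
                 dt = dt, type = "mean_removed", static = static,
                 valid = rep(TRUE, nrow(I))),
            class = "afc_map")
}

#' Extract one depth's autocorrelation profile from an `afc_map`
#'
#' @param map An `afc_map`.
#' @param depth Depth row index.
#' @return List of class `afc_profile` with `lags`, `values`, `dt`, `type`,
#'   and `static` flag.
#' @export
afc_profile <- function(map, depth = 1L) {
  stopifnot(inherits(map, "afc_map"), depth >= 1, depth <= nrow(map$values))
  structure(list(lags = map$lags, values = map$values[depth, ], dt = map$dt,
                 type = map$type,
                 static = if (!is.null(map$static)) map$static[depth] else FALSE),
            class = "afc_profile")
}
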