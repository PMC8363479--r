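#' Layer of a dynamic-speckle phantom
#'
#' Describes one tissue layer of a simulated sample: its depth extent, its
#' field decorrelation time, and its mean backscattered field magnitude.
#' A finite `tau_c` makes the layer dynamic (speckle decorrelates with field
#' autocorrelation `g1(tau) = exp(-tau/tau_c)`); `tau_c = Inf` makes it static.
#'
#' @param name Label for the layer (e.g. `"urothelium"`).
#' @param depth_range Integer vector of length 2, the half-open pixel interval
#'   `[z0, z1)` occupied by the layer; depth index 0 is the top (shallow) pixel.
#' @param tau_c Field decorrelation time in ms; positive, may be `Inf`.
#' @param amplitude Mean backscattered field magnitude (arbitrary units, >= 0).
#'
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(name, depth_range, tau_c = Inf, amplitude = 1) {
  stopifnot(length(depth_range) == 2)
  z0 <- depth_range[1]; z1 <- depth_range[2]
  if (!(z0 < z1)) stop("layer_spec: depth_range must satisfy z0 < z1")
  if (!(is.numeric(tau_c) && length(tau_c) == 1 && tau_c > 0))
    stop("layer_spec: tau_c must be a single positive value (Inf for static)")
  if (!(is.numeric(amplitude) && amplitude >= 0))
    stop("layer_spec: amplitude must be >= 0")
  structure(list(name = as.character(name),
                 depth_range = c(z0 = z0, z1 = z1),
                 tau_c = tau_c, amplitude = amplitude),
            class = "layer_spec")
}

#' Dynamic-speckle phantom specification
#'
#' Layered ground-truth description of a simulated spectral-domain OCT
#' acquisition. Defaults mirror a 20 kHz A-line-rate system recording M-scans
#' of 80,000 A-lines and B-scan stacks of 1000 A-lines at 20 frames/s.
#'
#' @param layers List of [layer_spec()] objects with non-overlapping depth
#'   ranges. Pixels covered by no layer contain pure noise.
#' @param n_depth Number of depth pixels.
#' @param n_time A-lines per M-scan.
#' @param dt A-line interval in ms (0.05 ms = 20 kHz).
#' @param n_alines A-lines per B-scan frame.
#' @param frame_rate_hz Frame rate used to derive `frame_interval` when the
#'   latter is not given; 20 frames/s gives 50 ms.
#' @param frame_interval ms between sequential frames; defaults to
#'   `1000 / frame_rate_hz`.
#' @param noise_sigma Standard deviation of additive complex circular Gaussian
#'   noise, per quadrature.
#' @param dynamic_cutoff tau_c (ms) below which a pixel counts as dynamic in
#'   the ground-truth mask.
#' @param seed RNG seed consumed by the simulators.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(layers, n_depth = 200L, n_time = 80000L, dt = 0.05,
                         n_alines = 1000L, frame_rate_hz = 20,
                         frame_interval = 1000 / frame_rate_hz,
                         noise_sigma = 0.05, dynamic_cutoff = 100,
                         seed = 1L) {
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_spec")))
  for (v in list(n_depth, n_time, n_alines))
    if (!(v == round(v) && v > 0)) stop("phantom_spec: counts must be positive integers")
  if (dt <= 0 || frame_interval <= 0) stop("phantom_spec: dt and frame_interval must be > 0")
  if (noise_sigma < 0) stop("phantom_spec: noise_sigma must be >= 0")
  rng <- vapply(layers, function(l) l$depth_range, numeric(2))
  if (length(layers) > 1) {
    o <- order(rng[1, ])
    if (any(rng[2, o][-length(layers)] > rng[1, o][-1]))
      stop("phantom_spec: layers have overlapping depth ranges")
  }
  if (any(rng[2, ] > n_depth)) stop("phantom_spec: layer exceeds n_depth")
  structure(list(layers = layers, n_depth = as.integer(n_depth),
                 n_time = as.integer(n_time), dt = dt,
                 n_alines = as.integer(n_alines),
                 frame_interval = frame_interval,
                 noise_sigma = noise_sigma,
                 dynamic_cutoff = dynamic_cutoff,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d depths, %d A-lines/M-scan @ dt = %g ms, %d A-lines/frame, frame interval %g ms, noise sigma %g, seed %d\n",
              x$n_depth, x$n_time, x$dt, x$n_alines, x$frame_interval,
              x$noise_sigma, x$seed))
  for (l in x$layers)
    cat(sprintf("  layer %-12s depths [%d, %d)  tau_c = %g ms  amplitude = %g\n",
                l$name, l$depth_range[1], l$depth_range[2], l$tau_c, l$amplitude))
  invisible(x)
}

# standard complex circular Gaussian draws: total variance sd^2
complex_rnorm <- function(n, sd = 1) {
  complex(real = stats::rnorm(n, sd = sd / sqrt(2)),
          imaginary = stats::rnorm(n, sd = sd / sqrt(2)))
}

#' Simulate a single-pixel complex speckle field trace
#'
#' Draws a stationary complex circular Gaussian first-order Markov process:
#' `E[1] ~ CN(0, amplitude^2)` and
#' `E[j+1] = rho * E[j] + amplitude * sqrt(1 - rho^2) * xi_j` with
#' `rho = exp(-dt / tau_c)` and `xi_j` iid standard complex circular Gaussian.
#' Its field autocorrelation is exactly `g1(tau) = exp(-tau/tau_c)`, so the
#' intensity autocorrelation obeys the Siegert relation
#' `G(tau) = 1 + exp(-2 tau / tau_c)`.
#'
#' Uses the session RNG; seed with [set.seed()] for reproducibility.
#'
#' @param tau_c Field decorrelation time in ms (positive; `Inf` = static).
#' @param amplitude Field magnitude scale (> 0).
#' @param dt Sample interval in ms.
#' @param n Number of samples.
#' @return Complex vector of length `n`.
#' @export
simulate_field_trace <- function(tau_c, amplitude, dt, n) {
  if (!(tau_c > 0)) stop("simulate_field_trace: tau_c must be > 0")
  if (!(amplitude > 0)) stop("simulate_field_trace: amplitude must be > 0")
  if (!(dt > 0)) stop("simulate_field_trace: dt must be > 0")
  if (!(n >= 1 && n == round(n))) stop("simulate_field_trace: n must be a positive integer")
  rho <- if (is.infinite(tau_c)) 1 else exp(-dt / tau_c)
  e1 <- complex_rnorm(1L, sd = amplitude)
  if (n == 1L) return(e1)
  if (rho == 1) return(rep(e1, n))
  w <- complex_rnorm(n - 1L, sd = amplitude * sqrt(1 - rho^2))
  re <- stats::filter(Re(w), rho, method = "recursive", init = Re(e1))
  im <- stats::filter(Im(w), rho, method = "recursive", init = Im(e1))
  c(e1, complex(real = as.numeric(re), imaginary = as.numeric(im)))
}

ground_truth_profile <- function(spec) {
  tau <- rep(Inf, spec$n_depth)
  amp <- rep(0, spec$n_depth)
  for (l in spec$layers) {
    z <- (l$depth_range[1] + 1L):l$depth_range[2]
    tau[z] <- l$tau_c
    amp[z] <- l$amplitude
  }
  list(tau_c = tau, amplitude = amp, dynamic = tau < spec$dynamic_cutoff)
}

#' Simulate an M-scan (depth x time complex field record)
#'
#' Each depth pixel carries an independent speckle trace with its layer's
#' decorrelation time and amplitude (see [simulate_field_trace()]); pixels
#' outside all layers are pure noise. Additive complex circular Gaussian
#' noise with `spec$noise_sigma` per quadrature is added everywhere.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `complex_mscan` with elements `field` (complex
#'   `n_depth x n_time` matrix), `dt` (ms), and `truth`: per-depth `tau_c_map`
#'   (ms, `Inf` = static) and `dynamic_mask`
#'   (`tau_c_map < spec$dynamic_cutoff`).
#' @export
simulate_mscan <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gt <- ground_truth_profile(spec)
  field <- matrix(0i, spec$n_depth, spec$n_time)
  for (z in seq_len(spec$n_depth))
    if (gt$amplitude[z] > 0)
      field[z, ] <- simulate_field_trace(gt$tau_c[z], gt$amplitude[z],
                                         spec$dt, spec$n_time)
  if (spec$noise_sigma > 0)
    field <- field + matrix(complex(
      real = stats::rnorm(length(field), sd = spec$noise_sigma),
      imaginary = stats::rnorm(length(field), sd = spec$noise_sigma)),
      spec$n_depth, spec$n_time)
  structure(list(field = field, dt = spec$dt,
                 truth = list(tau_c_map = gt$tau_c,
                              dynamic_mask = gt$dynamic)),
            class = "complex_mscan")
}

simulate_first_frame <- function(spec, gt) {
  f <- matrix(0i, spec$n_depth, spec$n_alines)
  for (z in seq_len(spec$n_depth))
    if (gt$amplitude[z] > 0)
      f[z, ] <- complex_rnorm(spec$n_alines, sd = gt$amplitude[z])
  f
}

evolve_frame <- function(f, spec, gt) {
  rho <- ifelse(is.infinite(gt$tau_c), 1, exp(-spec$frame_interval / gt$tau_c))
  innov_sd <- gt$amplitude * sqrt(pmax(0, 1 - rho^2))
  nxt <- f * rho
  for (z in seq_len(spec$n_depth))
    if (innov_sd[z] > 0)
      nxt[z, ] <- nxt[z, ] + complex_rnorm(spec$n_alines, sd = innov_sd[z])
  nxt
}

add_frame_noise <- function(f, sigma) {
  if (sigma <= 0) return(f)
  f + matrix(complex(real = stats::rnorm(length(f), sd = sigma),
                     imaginary = stats::rnorm(length(f), sd = sigma)),
             nrow(f), ncol(f))
}

#' Simulate a stack of sequential B-scan frames
#'
#' Frame-to-frame evolution follows the same first-order Markov recursion as
#' [simulate_field_trace()] with step `spec$frame_interval`, so the
#' pixel correlation between consecutive frames in a layer is
#' `rho = exp(-frame_interval / tau_c)`. Static pixels differ only by the
#' independent per-frame noise.
#'
#' @param spec A [phantom_spec()].
#' @param k Number of frames (`simulate_frame_pair()` is `k = 2`).
#' @return List of class `frame_stack` with `frames` (complex array
#'   `n_depth x n_alines x k`), `frame_interval` (ms), and `truth`: per-pixel
#'   `tau_c_map` and `dynamic_mask` matrices.
#' @export
simulate_frame_stack <- function(spec, k = 20L) {
  stopifnot(inherits(spec, "phantom_spec"), k >= 2, k == round(k))
  set.seed(spec$seed)
  gt <- ground_truth_profile(spec)
  frames <- array(0i, c(spec$n_depth, spec$n_alines, k))
  f <- simulate_first_frame(spec, gt)
  frames[, , 1] <- add_frame_noise(f, spec$noise_sigma)
  for (j in 2:k) {
    f <- evolve_frame(f, spec, gt)
    frames[, , j] <- add_frame_noise(f, spec$noise_sigma)
  }
  truth <- list(
    tau_c_map = matrix(gt$tau_c, spec$n_depth, spec$n_alines),
    dynamic_mask = matrix(gt$dynamic, spec$n_depth, spec$n_alines))
  structure(list(frames = frames, frame_interval = spec$frame_interval,
                 truth = truth),
            class = "frame_stack")
}

#' @rdname simulate_frame_stack
#' @export
simulate_frame_pair <- function(spec) simulate_frame_stack(spec, k = 2L)

#' Synthesize spectral fringes from a complex B-scan
#'
#' Inverse of the spectral-domain reconstruction: per A-line,
#' `fringe(k) = dc_level + 2 Re{ sum_z field(z) exp(+i 2 pi k z / n_k) }`
#' with depths placed at bins `z = 1..n_depth`, a real Hermitian-symmetric
#' synthesis such that [reconstruct_ascan()] recovers the field in the
#' positive-depth half to numerical precision.
#'
#' `n_k` must be at least `2 * (n_depth + 1)`: with fewer wavenumber samples
#' the deepest pixel would sit on (or alias past) the Nyquist bin, where a
#' real fringe cannot encode a complex value.
#'
#' @param field Complex matrix (`n_depth x n_alines`) or vector.
#' @param n_k Number of wavenumber samples; default `2 * (n_depth + 1)`.
#' @param dc_level Constant spectral offset added to every fringe.
#' @return A [spectral_frame()] whose `background` is the constant
#'   `dc_level` vector.
#' @export
synthesize_fringes <- function(field, n_k = NULL, dc_level = 0) {
  if (is.vector(field)) field <- matrix(field, ncol = 1)
  n_depth <- nrow(field)
  if (is.null(n_k)) n_k <- 2L * (n_depth + 1L)
  if (n_k < 2 * (n_depth + 1))
    stop("synthesize_fringes: n_k too small for n_depth (aliasing); need n_k >= 2*(n_depth+1)")
  spec <- matrix(0i, n_k, ncol(field))
  spec[1, ] <- dc_level
  spec[1 + seq_len(n_depth), ] <- field
  spec[n_k + 1 - seq_len(n_depth), ] <- Conj(field)
  fr <- Re(stats::mvfft(spec, inverse = TRUE))
  spectral_frame(fr, background = rep(dc_level, n_k))
}
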