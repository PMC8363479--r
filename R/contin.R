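#' Log-spaced decorrelation-time grid
#'
#' @param gamma_min,gamma_max Grid bounds in ms (default 0.01 to 1000 ms,
#'   bracketing the 0.1-30 ms decorrelation times typical of intracellular
#'   motion with wide margin).
#' @param n_gamma Number of grid points (default 100).
#' @return Object of class `dt_grid`: strictly increasing vector `gammas`.
#' @export
dt_grid <- function(gamma_min = 0.01, gamma_max = 1000, n_gamma = 100L) {
  stopifnot(gamma_min > 0, gamma_max > gamma_min, n_gamma >= 2)
  structure(list(gammas = 10^seq(log10(gamma_min), log10(gamma_max),
                                 length.out = n_gamma)),
            class = "dt_grid")
}

#' Exponential-decay design matrix
#'
#' `A[m, n] = exp(-t_m / gamma_n)`: column `n` is a unit-amplitude exponential
#' decay with decorrelation time `gamma_n` sampled at the lags, so a
#' nonnegative weight vector `x` models an autocorrelation tail as
#' `G = A x`, a sum of exponentials.
#'
#' @param lags Nonnegative lag times in ms.
#' @param grid A [dt_grid()] (or numeric vector of gammas).
#' @return Matrix of size `length(lags) x n_gamma` with attributes `lags`
#'   and `gammas`.
#' @export
build_design_matrix <- function(lags, grid) {
  gammas <- if (inherits(grid, "dt_grid")) grid$gammas else grid
  if (length(lags) == 0 || length(gammas) == 0)
    stop("build_design_matrix: empty lags or grid")
  stopifnot(all(lags >= 0), all(gammas > 0))
  A <- exp(-outer(lags, gammas, "/"))
  attr(A, "lags") <- lags
  attr(A, "gammas") <- gammas
  A
}

# finite-difference smoothness operator of the given order (no boundary rows)
smoothness_operator <- function(n, order = 2L) {
  if (n <= order) stop("smoothness_operator: grid too small for smoothing order")
  diff(diag(n), differences = order)
}

#' Smoothness-regularized nonnegative least squares
#'
#' Solves the Tikhonov-regularized nonnegative problem at the heart of the
#' CONTIN approach:
#' `min_{x >= 0} ||A x - G||^2 + alpha^2 ||Omega x||^2`,
#' where `Omega` is the finite-difference operator of order `smooth_order`
#' (default 2, a curvature penalty expressing that the decorrelation-time
#' distribution is continuous and smooth). Solved as ordinary nonnegative
#' least squares (Lawson-Hanson) on the stacked system
#' `[A; alpha Omega] x ~ [G; 0]`.
#'
#' @param A Design matrix from [build_design_matrix()].
#' @param G Autocorrelation values at the matrix's lags.
#' @param alpha Regularizer, `>= 0`.
#' @param smooth_order Order of the finite-difference penalty.
#' @param baseline If `TRUE`, augment the model with a free non-positive
#'   constant term (the classical CONTIN baseline). Subtracting the sample
#'   mean of a finite record before correlating depresses the autocovariance
#'   by a small constant, which nonnegative exponential sums cannot absorb
#'   and which would otherwise bias the recovered decorrelation times short;
#'   the baseline term soaks it up. It is excluded from the smoothness
#'   penalty and never reported as a peak.
#' @return Object of class `dt_distribution`: `gammas`, nonnegative `weights`,
#'   `alpha`, `baseline` (non-positive constant, 0 when disabled),
#'   `residual_norm = ||Ax + b - G||`, `seminorm = ||Omega x||`, and a
#'   `static` flag (always `FALSE` here).
#' @export
solve_regularized <- function(A, G, alpha, smooth_order = 2L, baseline = FALSE) {
  stopifnot(alpha >= 0, length(G) == nrow(A))
  gammas <- attr(A, "gammas")
  n <- ncol(A)
  Om <- smoothness_operator(n, smooth_order)
  Afit <- if (baseline) cbind(A, -1) else A
  Omfit <- if (baseline) cbind(Om, 0) else Om
  Astack <- if (alpha > 0) rbind(Afit, alpha * Omfit) else Afit
  bstack <- if (alpha > 0) c(G, numeric(nrow(Om))) else G
  sol <- tryCatch(pracma::lsqnonneg(Astack, bstack),
                  error = function(e) stop("solve_regularized: NNLS solver failed: ",
                                           conditionMessage(e)))
  xfull <- pmax(sol$x, 0)
  x <- xfull[seq_len(n)]
  b <- if (baseline) -xfull[n + 1] else 0
  structure(list(gammas = gammas, weights = x, alpha = alpha, baseline = b,
                 residual_norm = sqrt(sum((A %*% x + b - G)^2)),
                 seminorm = sqrt(sum((Om %*% x)^2)),
                 static = FALSE),
            class = "dt_distribution")
}

# Menger (three-point circumcircle) curvature at interior points of a
# polyline, using vertices span steps away; positive where the curve bends
# like an L-corner under increasing-alpha traversal
menger_curvature <- function(x, y, span = 1L) {
  n <- length(x)
  k <- rep(NA_real_, n)
  if (n < 2 * span + 1) return(k)
  for (i in (span + 1):(n - span)) {
    ax <- x[i - span]; ay <- y[i - span]
    bx <- x[i];        by <- y[i]
    cx <- x[i + span]; cy <- y[i + span]
    area2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- sqrt((bx - ax)^2 + (by - ay)^2)
    d2 <- sqrt((cx - bx)^2 + (cy - by)^2)
    d3 <- sqrt((cx - ax)^2 + (cy - ay)^2)
    if (d1 > 0 && d2 > 0 && d3 > 0) k[i] <- 2 * area2 / (d1 * d2 * d3)
  }
  k
}

# collapse runs of near-coincident log-log points to their last member:
# within a run the solution does not change, so the largest alpha achieving
# it is the honest representative, and coincident vertices would otherwise
# turn rounding noise into spurious curvature
dedupe_polyline <- function(lx, ly, tol = 1e-3) {
  n <- length(lx)
  keep <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && abs(lx[j + 1] - lx[i]) + abs(ly[j + 1] - ly[i]) < tol)
      j <- j + 1L
    keep <- c(keep, j)
    i <- j + 1L
  }
  keep
}

#' L-curve selection of the regularizer
#'
#' Solves the regularized problem over a grid of `alpha` values, plots (in
#' log-log coordinates) the residual norm `||Ax - G||` against the smoothness
#' seminorm `||Omega x||`, and returns the `alpha` of maximum curvature - the
#' L-curve corner, balancing data fidelity against smoothness. Ties break
#' toward smaller `alpha`. When the curvature is degenerate (too few usable
#' points) a triangle fallback (maximum deviation from the chord joining the
#' curve's endpoints) is used; if all residuals are equal the median `alpha`
#' is returned with a warning.
#'
#' @inheritParams solve_regularized
#' @param alpha_grid Strictly increasing positive grid of at least 5 alphas
#'   (default 50 log-spaced points over 1e-6 to 1e2).
#' @return List with `alpha` (the corner value) and `lcurve`, a data frame of
#'   class `lcurve` with columns `alpha`, `residual_norm`, `seminorm` and
#'   attribute `corner_index`.
#' @export
select_alpha_lcurve <- function(A, G, alpha_grid = 10^seq(-6, 2, length.out = 50),
                                smooth_order = 2L, baseline = FALSE) {
  stopifnot(length(alpha_grid) >= 5, all(alpha_grid > 0),
            all(diff(alpha_grid) > 0))
  sols <- lapply(alpha_grid, function(a)
    solve_regularized(A, G, a, smooth_order, baseline = baseline))
  rho <- vapply(sols, `[[`, numeric(1), "residual_norm")
  eta <- vapply(sols, `[[`, numeric(1), "seminorm")
  lc <- data.frame(alpha = alpha_grid, residual_norm = rho, seminorm = eta)
  class(lc) <- c("lcurve", "data.frame")

  corner <- NA_integer_
  if (diff(range(rho)) <= 1e-12 * max(rho, 1e-300)) {
    warning("select_alpha_lcurve: degenerate L-curve (flat residuals); using median alpha")
    corner <- as.integer(ceiling(length(alpha_grid) / 2))
  } else {
    usable <- which(rho > 0 & eta > 0)
    if (length(usable) >= 3) {
      lx <- log10(rho[usable]); ly <- log10(eta[usable])
      keep <- dedupe_polyline(lx, ly)
      span <- if (length(keep) >= 7) 2L else 1L
      if (length(keep) >= 3) {
        kap <- menger_curvature(lx[keep], ly[keep], span)
        if (any(is.finite(kap) & kap > 0))
          corner <- usable[keep[which.max(ifelse(is.finite(kap), kap, -Inf))]]
      }
    }
    if (is.na(corner)) {
      # triangle fallback: farthest point from the endpoint chord
      usable <- which(is.finite(rho) & is.finite(eta))
      lx <- log10(pmax(rho[usable], 1e-300))
      ly <- log10(pmax(eta[usable], 1e-300))
      x1 <- lx[1]; y1 <- ly[1]; x2 <- lx[length(lx)]; y2 <- ly[length(ly)]
      d <- abs((y2 - y1) * lx - (x2 - x1) * ly + x2 * y1 - y2 * x1)
      corner <- usable[which.max(d)]
    }
  }
  attr(lc, "corner_index") <- corner
  list(alpha = alpha_grid[corner], lcurve = lc)
}

#' Configuration for decorrelation-time inversion
#'
#' @param gamma_min,gamma_max,n_gamma Decorrelation-time grid, see [dt_grid()].
#' @param alphas Regularizer grid for L-curve selection.
#' @param alpha Optional fixed regularizer; skips L-curve selection when set.
#' @param smooth_order Order of the finite-difference smoothness penalty.
#' @param tau_min Shortest lag (ms) kept for fitting; `NULL` means the lag
#'   spacing `dt`, which excludes the tau = 0 point and with it the
#'   uncorrelated-noise spike.
#' @param tau_max Longest lag (ms) kept for fitting (default 50 ms, the
#'   extent of the decaying tail).
#' @param n_lags_fit Maximum number of (log-spaced) lags used in the fit;
#'   a densely sampled 50-ms window is decimated to this many channels.
#' @param baseline Fit a free non-positive constant alongside the
#'   exponentials (see [solve_regularized()]); on by default because the
#'   segmented mean-removed estimator carries a small negative offset.
#' @param static_threshold A mean-removed profile whose value at the first
#'   fitted lag falls below this is classified static (noise-only).
#' @param min_prominence_frac Default peak-prominence fraction for
#'   [find_dt_peaks()].
#' @return List of class `contin_config`.
#' @export
contin_config <- function(gamma_min = 0.01, gamma_max = 1000, n_gamma = 100L,
                          alphas = 10^seq(-6, 2, length.out = 50),
                          alpha = NULL, smooth_order = 2L, baseline = TRUE,
                          tau_min = NULL, tau_max = 50, n_lags_fit = 150L,
                          static_threshold = 0.1,
                          min_prominence_frac = 0.05) {
  structure(list(gamma_min = gamma_min, gamma_max = gamma_max,
                 n_gamma = as.integer(n_gamma), alphas = alphas, alpha = alpha,
                 smooth_order = as.integer(smooth_order),
                 baseline = baseline, tau_min = tau_min,
                 tau_max = tau_max, n_lags_fit = as.integer(n_lags_fit),
                 static_threshold = static_threshold,
                 min_prominence_frac = min_prominence_frac),
            class = "contin_config")
}

# log-spaced decimation of a lag index range, always keeping first and last
decimate_lags <- function(n_avail, n_keep) {
  if (n_avail <= n_keep) return(seq_len(n_avail))
  unique(round(10^seq(0, log10(n_avail), length.out = n_keep)))
}

static_distribution <- function(gammas, alpha = NA_real_) {
  structure(list(gammas = gammas, weights = numeric(length(gammas)),
                 alpha = alpha, baseline = 0, residual_norm = 0, seminorm = 0,
                 static = TRUE),
            class = "dt_distribution")
}

#' Invert an autocorrelation profile into a decorrelation-time distribution
#'
#' Full inversion for one depth: trims the profile to the fit window
#' `[tau_min, tau_max]` (dropping the tau = 0 noise spike), decimates the
#' lags to at most `n_lags_fit` log-spaced channels, builds the
#' exponential-decay design matrix on the configured gamma grid, selects the
#' regularizer at the L-curve corner (unless a fixed `alpha` is configured),
#' and solves the smoothness-regularized nonnegative problem.
#'
#' The input should be the mean-removed, tau = 0-normalized profile (see
#' [mean_removed_afc()]), which decays toward 0. A profile flagged static, or
#' whose value at the first fitted lag is below
#' `config$static_threshold`, returns an all-zero distribution tagged static.
#'
#' @param profile An `afc_profile` (see [afc_profile()]) or a list with
#'   `lags` and `values`.
#' @param config A [contin_config()].
#' @return A `dt_distribution` (see [solve_regularized()]) with the selected
#'   `alpha`, the `lcurve` attribute when L-curve selection ran, and fields
#'   `fit_lags` / `fit_values` recording the fitted window.
#' @export
invert_afc <- function(profile, config = contin_config()) {
  lags <- profile$lags
  values <- profile$values
  stopifnot(length(lags) == length(values))
  grid <- dt_grid(config$gamma_min, config$gamma_max, config$n_gamma)
  if (isTRUE(profile$static))
    return(static_distribution(grid$gammas))
  tau_min <- if (is.null(config$tau_min)) {
    dts <- diff(lags)
    if (length(dts)) min(dts) else 0
  } else config$tau_min
  keep <- which(lags >= tau_min - 1e-12 & lags <= config$tau_max + 1e-12)
  if (length(keep) < 3) stop("invert_afc: fewer than 3 lags in the fit window")
  lags_fit <- lags[keep]
  vals_fit <- values[keep]
  if (all(vals_fit == 0) || vals_fit[1] < config$static_threshold)
    return(static_distribution(grid$gammas))
  idx <- decimate_lags(length(lags_fit), config$n_lags_fit)
  lags_fit <- lags_fit[idx]
  vals_fit <- vals_fit[idx]
  A <- build_design_matrix(lags_fit, grid)
  lcv <- NULL
  alpha <- config$alpha
  if (is.null(alpha)) {
    sel <- select_alpha_lcurve(A, vals_fit, config$alphas, config$smooth_order,
                               baseline = config$baseline)
    alpha <- sel$alpha
    lcv <- sel$lcurve
  }
  dist <- solve_regularized(A, vals_fit, alpha, config$smooth_order,
                            baseline = config$baseline)
  dist$lcurve <- lcv
  dist$fit_lags <- lags_fit
  dist$fit_values <- vals_fit
  dist
}

#' Peaks of a decorrelation-time distribution
#'
#' Local maxima of the weights over the gamma grid whose topographic
#' prominence is at least `min_prominence_frac` times the maximum weight.
#' Plateaus count once (at their first grid point); prominences at the grid
#' boundary are measured down to the edge.
#'
#' @param dist A `dt_distribution`.
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   maximum weight (default 0.05).
#' @return Data frame with columns `gamma` (ms, on the grid), `weight`,
#'   `prominence`, sorted by `gamma`; zero rows for an empty distribution.
#' @export
find_dt_peaks <- function(dist, min_prominence_frac = 0.05) {
  w <- dist$weights
  g <- dist$gammas
  empty <- data.frame(gamma = numeric(0), weight = numeric(0),
                      prominence = numeric(0))
  if (all(w <= 0)) return(empty)
  n <- length(w)
  # plateau-aware local maxima
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nv <- length(r$values)
  is_peak_run <- vapply(seq_len(nv), function(i) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == nv || r$values[i + 1] < r$values[i]
    left_ok && right_ok && r$values[i] > 0
  }, logical(1))
  peak_idx <- starts[is_peak_run]
  if (!length(peak_idx)) return(empty)
  prominence <- vapply(peak_idx, function(i) {
    h <- w[i]
    left <- if (i > 1) w[seq_len(i - 1)] else numeric(0)
    right <- if (i < n) w[(i + 1):n] else numeric(0)
    base_side <- function(v) {
      # v ordered from the peak outward; descend to the edge or to the
      # foot of the first higher summit
      higher <- which(v > h)
      if (length(higher)) min(v[seq_len(higher[1] - 1)]) else min(v)
    }
    lb <- if (length(left)) base_side(rev(left)) else -Inf
    rb <- if (length(right)) base_side(right) else -Inf
    if (is.infinite(lb) && is.infinite(rb)) h else h - max(lb, rb)
  }, numeric(1))
  keep <- prominence >= min_prominence_frac * max(w)
  out <- data.frame(gamma = g[peak_idx[keep]], weight = w[peak_idx[keep]],
                    prominence = prominence[keep])
  out[order(out$gamma), , drop = FALSE]
}

#' Reconstruct an autocorrelation curve from a decorrelation-time distribution
#'
#' Evaluates `A x` - the sum of exponential decays weighted by the
#' distribution - at the requested lags, for overlaying on the measured curve.
#'
#' @param dist A `dt_distribution`.
#' @param lags Lag times in ms (default: the lags the distribution was
#'   fitted on).
#' @return Numeric vector of reconstructed values at `lags` (the fitted
#'   baseline, when any, is included).
#' @export
reconstruct_afc <- function(dist, lags = dist$fit_lags) {
  if (is.null(lags)) stop("reconstruct_afc: lags must be given")
  b <- if (is.null(dist$baseline)) 0 else dist$baseline
  as.numeric(build_design_matrix(lags, dist$gammas) %*% dist$weights) + b
}

#' Decorrelation-time depth map
#'
#' Runs [invert_afc()] on every depth of a (mean-removed) `afc_map`, on one
#' shared gamma grid. Static depths give all-zero rows; a per-depth failure
#' flags the row instead of aborting the map.
#'
#' @param afc_map An `afc_map`, normally from [mean_removed_afc()].
#' @param config A [contin_config()].
#' @return Object of class `dt_depth_map`: `gammas`, `weights`
#'   (depth x gamma matrix), per-depth `alpha`, `static` and `failed` flags.
#' @export
dt_depth_map <- function(afc_map, config = contin_config()) {
  stopifnot(inherits(afc_map, "afc_map"))
  n_depth <- nrow(afc_map$values)
  grid <- dt_grid(config$gamma_min, config$gamma_max, config$n_gamma)
  W <- matrix(0, n_depth, length(grid$gammas))
  alpha <- rep(NA_real_, n_depth)
  static <- rep(FALSE, n_depth)
  failed <- rep(FALSE, n_depth)
  for (z in seq_len(n_depth)) {
    res <- tryCatch(invert_afc(afc_profile(afc_map, z), config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[z] <- TRUE
    } else {
      W[z, ] <- res$weights
      alpha[z] <- res$alpha
      static[z] <- res$static
    }
  }
  structure(list(gammas = grid$gammas, weights = W, alpha = alpha,
                 static = static, failed = failed),
            class = "dt_depth_map")
}
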