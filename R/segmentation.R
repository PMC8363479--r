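#' Normalized two-frame complex difference
#'
#' The dynamic-contrast statistic computed from two sequential frames: per
#' A-line `i`,
#' `D_i = FT(sf1_i - sf2_i) / (|FT(sf1_i + sf2_i)| / 2 + eps)`,
#' the Fourier-domain difference normalized to the two frames' averaged
#' signal amplitude. Dynamic pixels, whose speckle field decorrelates between
#' the frames, give `|D|` of order 1 or larger; static pixels differ only by
#' noise and give `|D|` near zero. By linearity of the Fourier transform the
#' same statistic can be computed directly from two reconstructed complex
#' B-scans as `(F1 - F2) / (|F1 + F2|/2 + eps)`.
#'
#' When spectral frames are given, backgrounds are removed (via
#' [subtract_background()]) before transforming. The small `eps` guards the
#' division where the averaged amplitude is near zero; `valid_mask` marks
#' pixels whose averaged amplitude (before `eps`) exceeds the noise floor.
#' The floor is `mean + 2 SD` of the amplitude over `noise_region` rows when
#' supplied, a fixed `noise_floor` when given, and otherwise the same
#' statistic estimated from the dimmest decile of pixels.
#'
#' @param f1,f2 Two [spectral_frame()]s, two `complex_bscan`s, or two complex
#'   matrices of equal shape.
#' @param eps_frac Division guard as a fraction of the maximum averaged
#'   amplitude.
#' @param noise_floor Amplitude noise floor; overrides estimation.
#' @param noise_region Optional depth-row indices of a signal-free region used
#'   to estimate the noise floor.
#' @return Object of class `difference_image`: complex `D`, `magnitude`
#'   (`|D|`), logical `valid_mask`, and the `noise_floor` used.
#' @export
complex_difference <- function(f1, f2, eps_frac = 1e-6, noise_floor = NULL,
                               noise_region = NULL) {
  as_field <- function(f) {
    if (inherits(f, "spectral_frame")) {
      if (!isTRUE(f$bg_removed)) f <- subtract_background(f)
      reconstruct_ascan(f)$field
    } else if (inherits(f, "complex_bscan")) f$field
    else as.matrix(f)
  }
  F1 <- as_field(f1); F2 <- as_field(f2)
  if (!all(dim(F1) == dim(F2))) stop("complex_difference: frame shape mismatch")
  den <- Mod(F1 + F2) / 2
  eps <- eps_frac * max(den)
  D <- (F1 - F2) / (den + eps)
  if (is.null(noise_floor)) {
    amp <- if (!is.null(noise_region)) den[noise_region, , drop = FALSE]
           else den[den <= stats::quantile(den, 0.1)]
    noise_floor <- mean(amp) + 2 * stats::sd(amp)
    if (!is.finite(noise_floor)) noise_floor <- 0
  }
  structure(list(D = D, magnitude = Mod(D), valid_mask = den > noise_floor,
                 noise_floor = noise_floor),
            class = "difference_image")
}

#' Binary dynamic-tissue mask from a complex-difference image
#'
#' Thresholds `|D|` within the valid (above-noise-floor) pixels - by Otsu's
#' method on the (log-binned) magnitude histogram by default, or at a fixed
#' value - then cleans the binary image with a 3x3 median filter, 3x3
#' morphological closing, and removal of connected components smaller than
#' `min_size` pixels. All parameters used are recorded in the mask's
#' `provenance` attribute.
#'
#' `|D|` is a ratio of amplitudes, so its histogram is heavy-tailed; Otsu is
#' therefore computed on `log10 |D|`, where decorrelated and static speckle
#' form well-separated modes. Because `D` is normalized to the local signal
#' amplitude, full decorrelation gives `|D|` of order 2 regardless of
#' brightness; `min_threshold` (default 0.5) floors the data-driven threshold
#' at that physical scale so that a unimodal all-static image does not get
#' split down the middle.
#'
#' @param diff A `difference_image` from [complex_difference()].
#' @param threshold `"otsu"` or a fixed numeric threshold on `|D|`.
#' @param min_threshold Lower bound applied to the Otsu threshold (ignored
#'   for a fixed numeric `threshold`).
#' @param min_size Minimum connected-component area in pixels.
#' @param median_radius Radius of the median filter (1 = 3x3); 0 disables.
#' @param closing_size Side of the square closing brush; 0 disables.
#' @return Logical matrix of class `segmentation_mask` with attribute
#'   `provenance`.
#' @export
make_mask <- function(diff, threshold = "otsu", min_threshold = 0.5,
                      min_size = 25L, median_radius = 1L, closing_size = 3L) {
  stopifnot(inherits(diff, "difference_image"))
  mag <- diff$magnitude
  valid <- diff$valid_mask
  prov <- list(threshold = threshold, min_threshold = min_threshold,
               min_size = min_size, median_radius = median_radius,
               closing_size = closing_size, noise_floor = diff$noise_floor)
  if (!any(valid)) {
    warning("make_mask: empty valid mask; returning all-false mask")
    out <- matrix(FALSE, nrow(mag), ncol(mag))
    return(structure(out, provenance = prov, class = c("segmentation_mask", "matrix", "array")))
  }
  if (identical(threshold, "otsu")) {
    vals <- mag[valid & mag > 0]
    if (!length(vals)) {
      th <- Inf
    } else {
      lv <- log10(vals)
      rng <- range(lv)
      th <- if (diff(rng) == 0) Inf
            else {
        u <- EBImage::otsu(EBImage::Image(matrix((lv - rng[1]) / diff(rng),
                                                 nrow = 1)),
                           range = c(0, 1))
        max(10^(rng[1] + u * diff(rng)), min_threshold)
      }
    }
  } else {
    th <- as.numeric(threshold)
  }
  prov$threshold_value <- th
  bin <- valid & (mag > th)
  img <- EBImage::Image(bin * 1)
  if (median_radius > 0)
    img <- EBImage::medianFilter(img, size = median_radius) > 0.5
  if (closing_size > 0)
    img <- EBImage::closing(img > 0, EBImage::makeBrush(closing_size, "box"))
  lab <- EBImage::bwlabel(img > 0)
  labv <- as.integer(EBImage::imageData(lab))
  if (max(labv) > 0 && min_size > 1) {
    sizes <- tabulate(labv[labv > 0])
    keep <- which(sizes >= min_size)
    bin <- matrix(labv %in% keep, nrow(mag), ncol(mag))
  } else {
    bin <- matrix(labv > 0, nrow(mag), ncol(mag))
  }
  structure(bin, provenance = prov,
            class = c("segmentation_mask", "matrix", "array"))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param mask,truth Logical matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask, truth) {
  mask <- as.logical(mask); truth <- as.logical(truth)
  if (length(mask) != length(truth)) stop("dice: shape mismatch")
  denom <- sum(mask) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(mask & truth) / denom
}
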