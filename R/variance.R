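stack_intensities <- function(stack) {
  stopifnot(inherits(stack, "frame_stack") || (is.array(stack) && length(dim(stack)) == 3))
  fr <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (dim(fr)[3] < 2) stop("need at least 2 frames")
  if (is.complex(fr)) Mod(fr)^2 else fr
}

#' Average structural image of a frame stack
#'
#' Per-pixel mean of the intensity frames - the structural OCT image that
#' temporal averaging over a stack yields.
#'
#' @param stack A `frame_stack` (see [simulate_frame_stack()]) or a 3D array
#'   (depth x A-line x frame), complex field or intensity.
#' @return Nonnegative matrix (class `intensity_image`).
#' @export
average_image <- function(stack) {
  I <- stack_intensities(stack)
  out <- rowMeans(I, dims = 2)
  class(out) <- c("intensity_image", class(out))
  out
}

#' Normalized speckle-variance image
#'
#' Per-pixel variance of intensity across the frames (population form,
#' denominator `n`), normalized by its global maximum so values lie in
#' `[0, 1]`. Pixels whose speckle decorrelates between frames vary strongly
#' and light up; static pixels vary only by noise. An all-static stack (zero
#' variance everywhere) returns all zeros with a warning.
#'
#' With `smooth_radius > 0` the raw variance is boxcar-averaged over a
#' `(2r+1) x (2r+1)` window before normalization. A per-pixel variance of
#' fully developed speckle estimated from ~20 frames fluctuates by almost
#' its own magnitude, so a fixed fraction-of-maximum display threshold only
#' delineates a region after modest spatial averaging; the default leaves
#' the variance unsmoothed.
#'
#' @inheritParams average_image
#' @param smooth_radius Boxcar smoothing radius in pixels (0 = none).
#' @return Matrix in `[0, 1]` of class `variance_image` with attribute
#'   `n_frames`.
#' @export
variance_image <- function(stack, smooth_radius = 0L) {
  I <- stack_intensities(stack)
  k <- dim(I)[3]
  mu <- rowMeans(I, dims = 2)
  v <- rowMeans(I^2, dims = 2) - mu^2
  v[v < 0] <- 0  # numerical guard
  if (smooth_radius > 0) {
    side <- 2L * smooth_radius + 1L
    kern <- matrix(1 / side^2, side, side)
    v <- as.matrix(EBImage::filter2(EBImage::Image(v), kern,
                                    boundary = "replicate"))
    v[v < 0] <- 0
  }
  mx <- max(v)
  if (mx == 0) {
    warning("variance_image: no pixel varies; returning all zeros")
  } else {
    v <- v / mx
  }
  structure(v, n_frames = k, class = c("variance_image", class(v)))
}

# map a matrix through a color palette; returns H x W x 3 RGB array in [0,1]
colorize_matrix <- function(m, palette = grDevices::hcl.colors(256, "Inferno")) {
  rng <- range(m)
  idx <- if (diff(rng) == 0) rep(1L, length(m))
         else pmin(255L, pmax(0L, as.integer(round((m - rng[1]) / diff(rng) * 255)))) + 1L
  rgb <- grDevices::col2rgb(palette[idx]) / 255
  out <- array(0, c(nrow(m), ncol(m), 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, ], nrow(m), ncol(m))
  out
}

#' Fuse a structural image with a variance overlay
#'
#' Renders the structural image in grayscale and alpha-blends a color-mapped
#' variance overlay on top, with per-pixel opacity proportional to the
#' normalized variance. Pure visualization; deterministic for fixed inputs.
#'
#' @param avg Structural intensity image (e.g. from [average_image()]).
#' @param var Normalized variance image from [variance_image()], same shape.
#' @param palette Color palette for the overlay.
#' @param gamma Display gamma applied to the normalized structural image.
#' @return RGB array (`n_depth x n_alines x 3`, values in `[0, 1]`) suitable
#'   for [png::writePNG()].
#' @export
fuse_images <- function(avg, var, palette = grDevices::hcl.colors(256, "Inferno"),
                        gamma = 0.5) {
  avg <- unclass(avg); var <- unclass(var)
  if (!all(dim(avg) == dim(var))) stop("fuse_images: shape mismatch")
  mx <- max(avg)
  gray <- if (mx > 0) (avg / mx)^gamma else avg * 0
  color <- colorize_matrix(var, palette)
  out <- array(0, c(nrow(avg), ncol(avg), 3))
  for (ch in 1:3) out[, , ch] <- (1 - var) * gray + var * color[, , ch]
  out
}
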