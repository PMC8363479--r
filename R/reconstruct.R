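#' Raw spectral-fringe frame
#'
#' Container for spectral-domain OCT fringes: one column per A-line, one row
#' per wavenumber sample, with an optional prerecorded background spectrum
#' (the reference-arm signal measured with the sample arm blocked).
#'
#' @param fringes Real matrix, `n_k` wavenumber samples x `n_alines`.
#' @param background Optional real vector of length `n_k`.
#' @return Object of class `spectral_frame`.
#' @export
spectral_frame <- function(fringes, background = NULL) {
  fringes <- as.matrix(fringes)
  if (!all(is.finite(fringes))) stop("spectral_frame: fringes must be finite")
  if (!is.null(background) && length(background) != nrow(fringes))
    stop("spectral_frame: background length must match the number of wavenumber samples")
  structure(list(fringes = fringes, background = background,
                 bg_removed = FALSE),
            class = "spectral_frame")
}

#' Remove the DC / reference background from spectral fringes
#'
#' If the frame carries a prerecorded `background` spectrum it is subtracted
#' from every A-line (the blocked-sample-arm recording). Otherwise the
#' per-wavenumber mean across the frame's own A-lines is subtracted as a
#' fallback. The returned frame has its background consumed.
#'
#' @param frame A [spectral_frame()].
#' @return A [spectral_frame()] with zero-mean fringes and no background.
#' @export
subtract_background <- function(frame) {
  stopifnot(inherits(frame, "spectral_frame"))
  bg <- if (!is.null(frame$background)) frame$background
        else rowMeans(frame$fringes)
  out <- spectral_frame(frame$fringes - bg, background = NULL)
  out$bg_removed <- TRUE
  out
}

#' Reconstruct complex A-scans from spectral fringes
#'
#' Discrete Fourier transform along the wavenumber axis, per A-line, keeping
#' the positive-depth half (bins `1..floor(n_k/2)`; the DC bin is discarded).
#' No window and no zero-padding are applied by default. The transform is
#' scaled by `1/n_k` so that fringes from [synthesize_fringes()] reconstruct
#' to the original field values.
#'
#' @param frame A [spectral_frame()]. Background removal is the caller's
#'   responsibility (use [subtract_background()]); an unremoved DC offset only
#'   affects the discarded DC bin.
#' @param window `"none"` (default) or `"hann"` spectral apodization.
#' @return Object of class `complex_bscan`: list with complex matrix `field`
#'   (`floor(n_k/2) x n_alines`).
#' @export
reconstruct_ascan <- function(frame, window = c("none", "hann")) {
  stopifnot(inherits(frame, "spectral_frame"))
  window <- match.arg(window)
  n_k <- nrow(frame$fringes)
  if (n_k < 4) stop("reconstruct_ascan: need at least 4 wavenumber samples")
  fr <- frame$fringes
  if (window == "hann")
    fr <- fr * (0.5 - 0.5 * cos(2 * pi * (seq_len(n_k) - 1) / (n_k - 1)))
  full <- stats::mvfft(fr) / n_k
  structure(list(field = full[1 + seq_len(n_k %/% 2), , drop = FALSE]),
            class = "complex_bscan")
}

#' Intensity of a complex OCT signal
#'
#' Elementwise squared magnitude `|field|^2`.
#'
#' @param field A `complex_bscan`, a `complex_mscan`, or a complex matrix.
#' @return Nonnegative real matrix of the same shape.
#' @export
intensity <- function(field) {
  if (inherits(field, c("complex_bscan", "complex_mscan"))) field <- field$field
  Mod(field)^2
}
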