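#' Serialize a phantom specification to JSON
#'
#' Round-trips losslessly through [phantom_spec_from_json()]; `Inf`
#' decorrelation times are encoded as the string `"Inf"`.
#'
#' @param spec A [phantom_spec()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
phantom_spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$layers <- lapply(spec$layers, function(l) list(
    name = l$name, depth_range = as.integer(l$depth_range),
    tau_c = if (is.infinite(l$tau_c)) "Inf" else l$tau_c,
    amplitude = l$amplitude))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname phantom_spec_to_json
#' @param json A JSON string or file path produced by [phantom_spec_to_json()].
#' @export
phantom_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  layers <- lapply(x$layers, function(l)
    layer_spec(l$name, unlist(l$depth_range),
               tau_c = if (identical(l$tau_c, "Inf")) Inf else l$tau_c,
               amplitude = l$amplitude))
  phantom_spec(layers, n_depth = x$n_depth, n_time = x$n_time, dt = x$dt,
               n_alines = x$n_alines, frame_interval = x$frame_interval,
               noise_sigma = x$noise_sigma, dynamic_cutoff = x$dynamic_cutoff,
               seed = x$seed)
}

#' Write a real-valued image or mask to 32-bit float TIFF
#'
#' TIFF stores samples in `[0, 1]`, so images with a larger maximum are
#' scaled by `1 / max` before writing (the scale is returned invisibly);
#' quantitative values belong in the CSV writers.
#'
#' @param m Nonnegative numeric or logical matrix.
#' @param path Output file.
#' @return Invisibly, the scale factor the stored image was multiplied by.
#' @export
write_image_tiff <- function(m, path) {
  m <- unclass(m) * 1.0
  scale <- 1
  mx <- max(m)
  if (mx > 1) {
    scale <- 1 / mx
    m <- m * scale
  }
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' Write a matrix as a color-mapped PNG
#'
#' @param m Numeric matrix; mapped linearly onto the palette.
#' @param path Output file.
#' @param palette Color palette.
#' @export
write_colormap_png <- function(m, path, palette = grDevices::hcl.colors(256, "Inferno")) {
  png::writePNG(colorize_matrix(unclass(m), palette), path)
  invisible(path)
}

#' Write an autocorrelation map to CSV
#'
#' One row per depth, one column per lag (columns named `lag_<ms>`).
#'
#' @param map An `afc_map`.
#' @param path Output file.
#' @export
write_afc_csv <- function(map, path) {
  stopifnot(inherits(map, "afc_map"))
  df <- as.data.frame(map$values)
  names(df) <- sprintf("lag_%g", map$lags)
  df <- cbind(depth = seq_len(nrow(df)) - 1L, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a decorrelation-time depth map to CSV
#'
#' One row per depth, one column per gamma (columns named `gamma_<ms>`), plus
#' per-depth `alpha`, `static`, `failed`.
#'
#' @param map A `dt_depth_map`.
#' @param path Output file.
#' @export
write_dtmap_csv <- function(map, path) {
  stopifnot(inherits(map, "dt_depth_map"))
  df <- as.data.frame(map$weights)
  names(df) <- sprintf("gamma_%.4g", map$gammas)
  df <- cbind(depth = seq_len(nrow(df)) - 1L, alpha = map$alpha,
              static = map$static, failed = map$failed, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an L-curve to CSV
#' @param lcurve An `lcurve` data frame from [select_alpha_lcurve()].
#' @param path Output file.
#' @export
write_lcurve_csv <- function(lcurve, path) {
  df <- as.data.frame(lcurve)
  df$at_corner <- seq_len(nrow(df)) == attr(lcurve, "corner_index")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
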