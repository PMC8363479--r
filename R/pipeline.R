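#' Run configuration for the end-to-end workflows
#'
#' One flat configuration object with per-stage namespaces; round-trips
#' losslessly to and from JSON. When a pipeline runs with an `outdir`, the
#' resolved configuration is written beside the outputs and every artifact
#' set carries its MD5 hash for provenance.
#'
#' @param phantom A [phantom_spec()] describing the simulated input (or
#'   `NULL` when an M-scan / frame stack is passed to the pipeline directly).
#' @param afc List of [compute_afc()] parameters: `n_segments`, `max_lag`.
#' @param contin A [contin_config()].
#' @param segmentation List of [make_mask()] parameters: `threshold`,
#'   `min_size`, plus `eps_frac` for [complex_difference()].
#' @param n_frames Frames per stack for the segmentation pipeline.
#' @param seed Overrides the phantom's seed when not `NULL`.
#' @param outdir Output directory; `NULL` disables artifact writing.
#' @return List of class `dynoct_config`.
#' @export
dynoct_config <- function(phantom = NULL,
                          afc = list(n_segments = 20L, max_lag = 50),
                          contin = contin_config(),
                          segmentation = list(threshold = "otsu",
                                              min_size = 25L,
                                              eps_frac = 1e-6),
                          n_frames = 20L, seed = NULL, outdir = NULL) {
  structure(list(phantom = phantom, afc = afc, contin = contin,
                 segmentation = segmentation, n_frames = as.integer(n_frames),
                 seed = seed, outdir = outdir),
            class = "dynoct_config")
}

#' @rdname dynoct_config
#' @param config A `dynoct_config`.
#' @param path Optional file path for the JSON.
#' @export
config_to_json <- function(config, path = NULL) {
  x <- unclass(config)
  if (!is.null(x$phantom))
    x$phantom <- jsonlite::fromJSON(phantom_spec_to_json(config$phantom),
                                    simplifyDataFrame = FALSE)
  x$contin <- unclass(x$contin)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname dynoct_config
#' @param json JSON string or file path.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  phantom <- if (!is.null(x$phantom))
    phantom_spec_from_json(jsonlite::toJSON(x$phantom, auto_unbox = TRUE, digits = NA))
  co <- do.call(contin_config, x$contin[setdiff(names(x$contin), character(0))])
  dynoct_config(phantom = phantom, afc = x$afc, contin = co,
                segmentation = x$segmentation, n_frames = x$n_frames,
                seed = x$seed, outdir = x$outdir)
}

resolve_phantom <- function(config) {
  spec <- config$phantom
  if (is.null(spec)) stop("config carries no phantom spec and no input was given")
  if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
  spec
}

write_provenance <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.json")
  config_to_json(config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  writeLines(hash, file.path(outdir, "config.md5"))
  hash
}

#' M-scan analysis pipeline: autocorrelation then decorrelation-time mapping
#'
#' Simulates (or accepts) an M-scan, computes the raw and mean-removed
#' autocorrelation maps, inverts every depth into a decorrelation-time
#' distribution, and tabulates the peaks per depth. With an `outdir`, writes
#' the AFC and DT maps as CSV and color-mapped PNG, the peak table as CSV,
#' and the resolved config JSON + MD5 for provenance.
#'
#' @param config A [dynoct_config()].
#' @param mscan Optional `complex_mscan`; when `NULL` the config's phantom is
#'   simulated.
#' @return List with `afc_raw`, `afc_mr` (both `afc_map`), `dt_map`
#'   (`dt_depth_map`), `peaks` (data frame `depth`, `gamma`, `weight`,
#'   `prominence`), and `truth` when simulated.
#' @export
run_mscan_pipeline <- function(config = dynoct_config(), mscan = NULL) {
  truth <- NULL
  if (is.null(mscan)) {
    mscan <- simulate_mscan(resolve_phantom(config))
    truth <- mscan$truth
  }
  afc_raw <- compute_afc(mscan, n_segments = config$afc$n_segments,
                         max_lag = config$afc$max_lag)
  afc_mr <- mean_removed_afc(mscan, n_segments = config$afc$n_segments,
                             max_lag = config$afc$max_lag)
  dt_map <- dt_depth_map(afc_mr, config$contin)
  peaks <- do.call(rbind, lapply(seq_len(nrow(dt_map$weights)), function(z) {
    d <- structure(list(gammas = dt_map$gammas, weights = dt_map$weights[z, ]),
                   class = "dt_distribution")
    p <- find_dt_peaks(d, config$contin$min_prominence_frac)
    if (nrow(p)) cbind(depth = z - 1L, p) else NULL
  }))
  if (is.null(peaks))
    peaks <- data.frame(depth = integer(0), gamma = numeric(0),
                        weight = numeric(0), prominence = numeric(0))
  if (!is.null(config$outdir)) {
    out <- config$outdir
    write_provenance(config, out)
    write_afc_csv(afc_raw, file.path(out, "afc_raw.csv"))
    write_afc_csv(afc_mr, file.path(out, "afc_mean_removed.csv"))
    write_colormap_png(afc_mr$values, file.path(out, "afc_map.png"))
    write_dtmap_csv(dt_map, file.path(out, "dt_map.csv"))
    write_colormap_png(dt_map$weights, file.path(out, "dt_map.png"))
    utils::write.csv(peaks, file.path(out, "dt_peaks.csv"), row.names = FALSE)
  }
  list(afc_raw = afc_raw, afc_mr = afc_mr, dt_map = dt_map, peaks = peaks,
       truth = truth)
}

#' Segmentation pipeline: speckle variance and two-frame dynamic contrast
#'
#' Simulates (or accepts) a frame stack, computes the normalized speckle
#' variance over all frames, the averaged structural image and their fusion,
#' then the two-frame complex-difference segmentation from frames 1 and 2.
#' When ground truth is available the Dice overlap and false-positive rate
#' are reported. With an `outdir`, writes variance/average TIFFs, the fused
#' overlay and mask PNGs, metrics JSON, and config provenance.
#'
#' @param config A [dynoct_config()].
#' @param stack Optional `frame_stack`; when `NULL` the config's phantom is
#'   simulated with `config$n_frames` frames.
#' @return List with `variance`, `average`, `fused`, `diff`
#'   (`difference_image`), `mask` (`segmentation_mask`), and `metrics`
#'   (`dice`, `false_positive_rate`, or both `NA` without ground truth).
#' @export
run_segmentation_pipeline <- function(config = dynoct_config(), stack = NULL) {
  if (is.null(stack))
    stack <- simulate_frame_stack(resolve_phantom(config), k = config$n_frames)
  vimg <- variance_image(stack)
  aimg <- average_image(stack)
  fused <- fuse_images(aimg, vimg)
  sg <- config$segmentation
  # signal-free depth rows of the phantom, if any, anchor the noise floor
  noise_region <- NULL
  if (!is.null(config$phantom)) {
    amp <- rep(0, config$phantom$n_depth)
    for (l in config$phantom$layers)
      amp[(l$depth_range[1] + 1):l$depth_range[2]] <- l$amplitude
    if (any(amp == 0)) noise_region <- which(amp == 0)
  }
  dimg <- complex_difference(stack$frames[, , 1], stack$frames[, , 2],
                             eps_frac = sg$eps_frac,
                             noise_region = noise_region)
  mask <- make_mask(dimg, threshold = sg$threshold, min_size = sg$min_size)
  metrics <- list(dice = NA_real_, false_positive_rate = NA_real_)
  truth <- stack$truth
  if (!is.null(truth)) {
    metrics$dice <- if (any(truth$dynamic_mask)) dice(mask, truth$dynamic_mask)
                    else NA_real_
    metrics$false_positive_rate <- sum(mask & !truth$dynamic_mask) /
      sum(!truth$dynamic_mask)
  }
  if (!is.null(config$outdir)) {
    out <- config$outdir
    write_provenance(config, out)
    write_image_tiff(vimg, file.path(out, "variance.tiff"))
    write_image_tiff(aimg, file.path(out, "average.tiff"))
    png::writePNG(fused, file.path(out, "fused.png"))
    write_image_tiff(dimg$magnitude, file.path(out, "difference_magnitude.tiff"))
    png::writePNG(unclass(mask) * 1.0, file.path(out, "mask.png"))
    jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(variance = vimg, average = aimg, fused = fused, diff = dimg,
       mask = mask, metrics = metrics, truth = truth)
}
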