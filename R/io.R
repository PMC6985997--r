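# TIFF I/O. Multi-channel movies are stored channel-interleaved page order
# (frame 1 ch 1, frame 1 ch 2, ..., frame 2 ch 1, ...), 16-bit unsigned.
# Intensities are kept as raw counts (0..65535); writing rounds to integers, so
# a round trip is lossless for integer-valued data.

#' Load a time-lapse movie from TIFF / OME-TIFF
#'
#' Pages are interpreted as channel-interleaved frames: with C channels, page
#' \code{(f - 1) * C + c} holds frame f of channel c.
#'
#' @param path readable TIFF file.
#' @param channel_map named list/vector mapping channel names to 1-based channel
#'   indices, e.g. \code{c(gata1 = 1, gcamp = 2)}.
#' @param fps acquisition rate (Hz).
#' @param pixel_size in-plane pixel pitch (micrometres).
#' @param stimulus_onset,stimulus_duration stimulus timing metadata (seconds).
#' @return an \code{nvc_movie}; intensities preserved losslessly as integer
#'   counts.
#' @export
load_movie <- function(path, channel_map = c(ch1 = 1), fps, pixel_size,
                       stimulus_onset = 0, stimulus_duration = 0) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- unique(lapply(pages, dim))
  if (length(shp) != 1L)
    stop("format error: TIFF pages have non-uniform frame shape")
  idx <- unlist(channel_map)
  n_ch <- max(idx)
  if (length(pages) %% n_ch != 0L)
    stop("configuration error: page count ", length(pages),
         " is not a multiple of the channel count ", n_ch)
  if (any(idx < 1L | idx > n_ch))
    stop("configuration error: channel index out of range")
  n_t <- length(pages) %/% n_ch
  frames <- lapply(idx, function(ci) {
    sel <- pages[seq.int(ci, by = n_ch, length.out = n_t)]
    arr <- array(0, dim = c(n_t, nrow(sel[[1]]), ncol(sel[[1]])))
    for (f in seq_len(n_t)) arr[f, , ] <- sel[[f]]
    arr
  })
  names(frames) <- names(channel_map)
  time_series_movie(frames, fps = fps, pixel_size = pixel_size,
                    stimulus_onset = stimulus_onset,
                    stimulus_duration = stimulus_duration)
}

#' Write a movie to multi-page TIFF
#'
#' @param movie an \code{nvc_movie}; intensities must lie in [0, 65535].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$frames[[1]])
  n_ch <- length(movie$frames)
  pages <- vector("list", d[1] * n_ch)
  for (f in seq_len(d[1]))
    for (c in seq_len(n_ch)) {
      m <- movie$frames[[c]][f, , ]
      if (min(m) < 0 || max(m) > 65535) stop("intensities must be in [0, 65535]")
      pages[[(f - 1L) * n_ch + c]] <- round(m) / 65535
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Load a Z-stack from TIFF
#'
#' @param path readable TIFF; pages are channel-interleaved slices.
#' @param channel_map named vector of 1-based channel indices.
#' @param voxel_size length-3 \code{(z, y, x)} micrometre pitch.
#' @return an \code{nvc_zstack}.
#' @export
load_stack <- function(path, channel_map = c(ch1 = 1), voxel_size = c(1, 1, 1)) {
  mv <- load_movie(path, channel_map, fps = 1, pixel_size = 1)
  z_stack(mv$frames, voxel_size = voxel_size)
}

#' Write a Z-stack to multi-page TIFF
#' @param stack an \code{nvc_zstack}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_stack <- function(stack, path) {
  mv <- time_series_movie(stack$voxels, fps = 1, pixel_size = 1)
  write_movie(mv, path)
}

#' Write a ground-truth sidecar as JSON
#'
#' Truth sidecars record the generator seed and the analytic ground truth of a
#' synthetic dataset, sufficient to reproduce the imagery bit-for-bit.
#'
#' @param truth a list (generator-specific schema).
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path JSON path.
#' @return list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read an experiment configuration (YAML)
#'
#' One file carries acquisition constants (fps, pixel_size, window lengths),
#' per-module parameter blocks, group layout and the root seed. Defaults are
#' filled for any missing field; see \code{default_config()}.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides named list merged over the file contents (CLI flags).
#' @return validated config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- modifyList(default_config(), modifyList(cfg, overrides))
  validate_config(cfg)
  cfg
}

#' Default experiment configuration
#'
#' Acquisition constants follow the lightsheet protocol: 32 frames/s,
#' 0.609 um/pixel, 29 s pre-stimulus baseline imaging, 8 s visual stimulus.
#' Analysis windows: baseline \code{[-10, 0)}, response \code{[0, 20)},
#' recovery \code{[20, 30)} s.
#'
#' @return named list of parameter blocks.
#' @export
default_config <- function() {
  list(
    fps = 32, pixel_size = 0.609,
    stimulus_onset = 29, stimulus_duration = 8,
    baseline_len = 10, response_len = 20, recovery_len = 10,
    rbc = list(threshold = 0.5, min_area = 2, max_area = 200,
               median_filter = TRUE, max_disp = 20, max_gap = 2,
               smooth_bin_s = 3, max_interp_gap_s = 1),
    calcium = list(k_sd = 2, min_separation = 1, abs_threshold = 0.05,
                   baseline_window = 10),
    vessels = list(min_size = 50, bright_vessels = TRUE,
                   junction_cluster_px = 2, prune_px = 5, spur_px = 5),
    stats = list(alpha = 0.05, shapiro_alpha = 0.05, gg_eps_threshold = 0.75,
                 average_trials = TRUE),
    seed = 1
  )
}

validate_config <- function(cfg) {
  stopifnot(cfg$fps > 0, cfg$pixel_size > 0,
            cfg$baseline_len > 0, cfg$response_len > 0, cfg$recovery_len > 0,
            cfg$stimulus_duration >= 0,
            cfg$rbc$max_disp > 0, cfg$rbc$smooth_bin_s > 0,
            cfg$calcium$k_sd > 0, cfg$stats$alpha > 0, cfg$stats$alpha < 1)
  invisible(cfg)
}

#' Derive a per-stage RNG seed from one root seed
#'
#' All randomness in an experiment flows from a single root seed through this
#' deterministic map, so one number reproduces every stage. Results stay
#' below 2^31.
#'
#' @param root integer root seed.
#' @param stage stage name (any string).
#' @param index replicate index within the stage.
#' @return integer seed.
#' @export
derive_seed <- function(root, stage, index = 0L) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(root) * 1103L + stage_code * 211L + as.integer(index) * 7L) %% 2147483647L
}
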