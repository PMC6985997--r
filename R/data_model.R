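#' @importFrom stats approx sd shapiro.test aov pf friedman.test t.test
#'   wilcox.test optimize setNames complete.cases rnorm runif rpois quantile
#'   cov dist
#' @importFrom utils write.csv read.csv modifyList combn
#' @importFrom tools md5sum
NULL

# Shared conventions: image origin top-left, (y, x) ordering, 0-based pixel
# coordinates (pixel centres at integers 0..n-1); arrays are stored 1-based as
# [t, y, x] / [z, y, x]. Time is in seconds relative to stimulus onset (t = 0);
# all period windows are half-open [start, end).

#' Construct a multi-channel time-lapse movie
#'
#' Container for a single-plane fluorescence time series with acquisition
#' metadata. All channels must share one \code{(time, y, x)} shape. Time zero
#' is stimulus onset; the first frame of the file maps to
#' \code{t = -stimulus_onset}.
#'
#' @param frames a numeric array \code{[t, y, x]} or a named list of such
#'   arrays, one per channel.
#' @param fps acquisition rate in frames per second (Hz), > 0.
#' @param pixel_size in-plane pixel size in micrometres (isotropic); anisotropic
#'   pixels are rejected, pass a single value.
#' @param stimulus_onset seconds from the start of the file to stimulus onset.
#' @param stimulus_duration stimulus length in seconds (>= 0).
#' @return an object of class \code{nvc_movie} with fields \code{frames}
#'   (named list of arrays), \code{fps}, \code{pixel_size},
#'   \code{stimulus_onset}, \code{stimulus_duration} and derived
#'   \code{duration} = n_frames / fps.
#' @export
time_series_movie <- function(frames, fps, pixel_size,
                              stimulus_onset = 0, stimulus_duration = 0) {
  if (is.array(frames) && length(dim(frames)) == 3L) frames <- list(ch1 = frames)
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a [t, y, x] array or a non-empty named list of them")
  if (is.null(names(frames)) || any(!nzchar(names(frames))))
    stop("channels must be named")
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3-d [t, y, x] array")
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channels must share an identical (time, y, x) shape")
  if (length(pixel_size) == 2L) {
    if (abs(pixel_size[1] - pixel_size[2]) > 1e-9)
      stop("anisotropic in-plane pixels are not supported")
    pixel_size <- pixel_size[1]
  }
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0,
            is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            stimulus_duration >= 0)
  n <- dims[[1]][1]
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 duration = n / fps),
            class = "nvc_movie")
}

#' @export
print.nvc_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<nvc_movie> %d frame(s) of %d x %d px, channels: %s\n  fps %g Hz, pixel %g um, duration %g s, stimulus onset %g s (dur %g s)\n",
    d[1], d[2], d[3], paste(names(x$frames), collapse = ", "),
    x$fps, x$pixel_size, x$duration, x$stimulus_onset, x$stimulus_duration))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie an \code{nvc_movie}.
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames[[1]])[1]

#' Frame timestamps relative to stimulus onset
#'
#' @param movie an \code{nvc_movie}.
#' @return numeric vector of length \code{n_frames(movie)}; frame i (1-based)
#'   maps to \code{(i - 1) / fps - stimulus_onset} seconds.
#' @export
frame_times <- function(movie) {
  (seq_len(n_frames(movie)) - 1) / movie$fps - movie$stimulus_onset
}

#' Construct a 3-D image stack
#'
#' @param voxels a numeric array \code{[z, y, x]} or named list of such arrays.
#' @param voxel_size numeric length-3 \code{(z, y, x)} voxel pitch in
#'   micrometres, all > 0.
#' @return an object of class \code{nvc_zstack}.
#' @export
z_stack <- function(voxels, voxel_size) {
  if (is.array(voxels) && length(dim(voxels)) == 3L) voxels <- list(ch1 = voxels)
  if (!is.list(voxels) || length(voxels) == 0L || is.null(names(voxels)))
    stop("`voxels` must be a [z, y, x] array or a named list of them")
  dims <- lapply(voxels, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      length(unique(lapply(dims, identity))) != 1L)
    stop("all channels must be 3-d arrays of identical shape")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size)),
            class = "nvc_zstack")
}

#' @export
print.nvc_zstack <- function(x, ...) {
  d <- dim(x$voxels[[1]])
  cat(sprintf("<nvc_zstack> %d x %d x %d (z,y,x), voxel %s um, channels: %s\n",
              d[1], d[2], d[3], paste(x$voxel_size, collapse = " x "),
              paste(names(x$voxels), collapse = ", ")))
  invisible(x)
}

#' Define baseline / response / recovery windows
#'
#' Windows are half-open intervals in seconds relative to stimulus onset:
#' baseline \code{[-baseline_len, 0)}, response \code{[0, response_len)},
#' recovery \code{[response_len, response_len + recovery_len)}. A sample at
#' exactly t = 0 belongs to the response window.
#'
#' @param stimulus_onset seconds from file start to stimulus onset (metadata,
#'   recorded but not used for the relative window positions).
#' @param stimulus_duration stimulus length in seconds.
#' @param baseline_len,response_len,recovery_len window lengths in seconds,
#'   all > 0.
#' @return an object of class \code{nvc_periods}: named list of length-2
#'   numeric \code{c(start, end)} vectors.
#' @export
define_periods <- function(stimulus_onset = 29, stimulus_duration = 8,
                           baseline_len = 10, response_len = 20,
                           recovery_len = 10) {
  if (any(c(baseline_len, response_len, recovery_len) <= 0))
    stop("window lengths must be > 0")
  structure(list(baseline = c(-baseline_len, 0),
                 response = c(0, response_len),
                 recovery = c(response_len, response_len + recovery_len),
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration),
            class = "nvc_periods")
}

#' @export
print.nvc_periods <- function(x, ...) {
  for (p in c("baseline", "response", "recovery"))
    cat(sprintf("  %-8s [%g, %g) s\n", p, x[[p]][1], x[[p]][2]))
  invisible(x)
}

#' Half-open window membership
#'
#' @param t numeric times in seconds (relative to stimulus onset).
#' @param window length-2 \code{c(start, end)} or a window name plus
#'   a \code{nvc_periods} object.
#' @param periods optional \code{nvc_periods} when \code{window} is a name.
#' @return logical vector, TRUE where \code{start <= t < end}.
#' @export
in_window <- function(t, window, periods = NULL) {
  if (is.character(window)) window <- periods[[window]]
  t >= window[1] & t < window[2]
}

period_names <- c("baseline", "response", "recovery")

#' Assemble result-table rows
#'
#' The long-format result table keys every measured value by
#' \code{(animal_id, group, trial, period, metric)} and tags its units.
#'
#' @param animal_id,group,trial,period,metric,value,units row fields (recycled).
#' @return a data.frame with the seven canonical columns.
#' @export
result_rows <- function(animal_id, group, trial, period, metric, value, units) {
  data.frame(animal_id = animal_id, group = group, trial = trial,
             period = period, metric = metric, value = value, units = units,
             stringsAsFactors = FALSE)
}

#' Validate and write a result table to CSV
#'
#' @param tab a data.frame of \code{result_rows}.
#' @param path output CSV path.
#' @return invisibly, the normalised table (sorted by key).
#' @export
write_result_table <- function(tab, path) {
  cols <- c("animal_id", "group", "trial", "period", "metric", "value", "units")
  if (!all(cols %in% names(tab))) stop("result table is missing key columns")
  if (any(!nzchar(tab$units))) stop("every row must carry a units tag")
  key <- do.call(paste, c(tab[c("animal_id", "group", "trial", "period", "metric")],
                          sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate (animal, group, trial, period, metric) keys")
  tab <- tab[order(tab$animal_id, tab$group, tab$trial, tab$period, tab$metric), cols]
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read a result table written by \code{write_result_table}
#' @param path CSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
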