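# Neuronal activation from the tectal calcium channel. dF/F is background- and
# baseline-corrected:  dF/F = ((F - B) - (Fo - Bo)) / (Fo - Bo), with Fo, Bo
# the 10 s pre-stimulus means of the tectal and background ROI traces.

#' Compute the background-corrected dF/F trace
#'
#' \code{F} and \code{B} are per-frame means over the tectal and background
#' ROIs; \code{Fo}, \code{Bo} are their means over the pre-stimulus baseline
#' window (default 10 s before onset).
#'
#' @param movie an \code{nvc_movie}.
#' @param tectum_roi,background_roi disjoint, non-empty logical masks of the
#'   frame shape.
#' @param channel channel name (default first channel).
#' @param baseline_window seconds before stimulus onset averaged for
#'   \code{Fo}/\code{Bo}; must fit before onset.
#' @return a \code{calcium_trace}: list with \code{t} (s, relative to onset),
#'   \code{dff}, \code{F}, \code{B}, \code{F_o}, \code{B_o}, \code{fps}.
#' @export
compute_dff <- function(movie, tectum_roi, background_roi,
                        channel = names(movie$frames)[1],
                        baseline_window = 10) {
  if (!channel %in% names(movie$frames)) stop("no channel named ", channel)
  arr <- movie$frames[[channel]]
  d <- dim(arr)
  if (!identical(dim(tectum_roi), d[2:3]) ||
      !identical(dim(background_roi), d[2:3]))
    stop("ROI masks must match the frame shape")
  if (!any(tectum_roi) || !any(background_roi)) stop("ROIs must be non-empty")
  if (any(tectum_roi & background_roi)) stop("ROIs must be disjoint")
  if (baseline_window > movie$stimulus_onset + 1e-9)
    stop("baseline window does not fit before stimulus onset")
  tt <- frame_times(movie)
  flat <- matrix(arr, nrow = d[1])            # frames x pixels
  Ftr <- rowMeans(flat[, which(tectum_roi), drop = FALSE])
  Btr <- rowMeans(flat[, which(background_roi), drop = FALSE])
  base <- in_window(tt, c(-baseline_window, 0))
  if (!any(base)) stop("no frames in the pre-stimulus baseline window")
  F_o <- mean(Ftr[base]); B_o <- mean(Btr[base])
  if (F_o - B_o <= 0)
    stop("invalid trace: baseline tectal signal does not exceed background (F_o - B_o <= 0)")
  dff <- ((Ftr - Btr) - (F_o - B_o)) / (F_o - B_o)
  structure(list(t = tt, dff = dff, F = Ftr, B = Btr, F_o = F_o, B_o = B_o,
                 fps = movie$fps),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d frames @ %g Hz, dF/F range [%.3g, %.3g]\n",
              length(x$t), x$fps, min(x$dff), max(x$dff)))
  invisible(x)
}

#' Detect calcium transient peaks
#'
#' Local maxima of dF/F exceeding \code{k_sd} baseline standard deviations,
#' separated by at least \code{min_separation} seconds (larger peaks suppress
#' smaller neighbours). Amplitude is measured from the preceding local minimum.
#' \code{abs_threshold} is an absolute dF/F floor under the statistical
#' threshold: it keeps sub-physiological ripples out of very quiet recordings
#' and is the only active threshold on a noiseless trace.
#'
#' @param ct a \code{calcium_trace}.
#' @param k_sd threshold in baseline s.d. units (default 2).
#' @param min_separation minimum peak spacing in seconds (default 1).
#' @param baseline window \code{c(start, end)} in seconds defining baseline
#'   variance (default \code{c(-10, 0)}).
#' @param abs_threshold absolute dF/F detection floor.
#' @return a \code{peak_set}: data.frame with \code{time}, \code{dff},
#'   \code{amplitude}, \code{frame}; attribute \code{threshold}.
#' @export
detect_peaks <- function(ct, k_sd = 2, min_separation = 1,
                         baseline = c(-10, 0), abs_threshold = 0.05) {
  v <- ct$dff
  base_sd <- sd(v[in_window(ct$t, baseline)])
  thr <- max(if (is.na(base_sd)) 0 else k_sd * base_sd, abs_threshold)
  n <- length(v)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_max & v > thr)
  # non-maximum suppression within min_separation, strongest first
  cand <- cand[order(-v[cand], ct$t[cand])]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(ct$t[i] - ct$t[kept]) >= min_separation))
      kept <- c(kept, i)
  kept <- sort(kept)
  amp <- vapply(kept, function(i) {
    j <- i
    while (j > 1L && v[j - 1L] <= v[j]) j <- j - 1L   # walk down to local min
    v[i] - v[j]
  }, numeric(1))
  structure(data.frame(time = ct$t[kept], dff = v[kept], amplitude = amp,
                       frame = kept),
            threshold = thr, class = c("peak_set", "data.frame"))
}

#' Per-period peak counts and rates
#'
#' @param ps a \code{peak_set}.
#' @param windows an \code{nvc_periods}.
#' @return data.frame with \code{period}, \code{count}, \code{rate_hz}
#'   (count / window length).
#' @export
peak_frequency <- function(ps, windows) {
  out <- lapply(period_names, function(p) {
    w <- windows[[p]]
    cnt <- sum(in_window(ps$time, w))
    data.frame(period = p, count = cnt, rate_hz = cnt / diff(w))
  })
  do.call(rbind, out)
}

#' Latency metrics for a stimulus-locked peak
#'
#' \code{time_to_peak} is the latency from the stimulus event to the peak;
#' \code{t_half} is the first time after the event at which dF/F crosses half
#' the peak amplitude (sub-frame, by linear interpolation between the
#' bracketing samples).
#'
#' @param ct a \code{calcium_trace}.
#' @param peak_time peak time in seconds (e.g. a \code{peak_set} row).
#' @param event_time stimulus event (onset or offset) in seconds; must precede
#'   the peak.
#' @return list with \code{time_to_peak} and \code{t_half} (NA with a warning
#'   if no half-crossing exists).
#' @export
peak_timing <- function(ct, peak_time, event_time) {
  if (event_time > peak_time) stop("event_time must precede the peak")
  i_peak <- which.min(abs(ct$t - peak_time))
  sel <- which(ct$t >= event_time & ct$t <= ct$t[i_peak])
  ref <- ct$dff[sel[1]]
  half <- ref + (ct$dff[i_peak] - ref) / 2
  above <- ct$dff[sel] >= half
  k <- which(above)[1]
  t_half <- if (is.na(k)) {
    warning("no half-amplitude crossing found after the event")
    NA_real_
  } else if (k == 1L) {
    ct$t[sel[1]] - event_time
  } else {
    i0 <- sel[k - 1L]; i1 <- sel[k]
    frac <- (half - ct$dff[i0]) / (ct$dff[i1] - ct$dff[i0])
    (ct$t[i0] + frac * (ct$t[i1] - ct$t[i0])) - event_time
  }
  list(time_to_peak = peak_time - event_time, t_half = t_half)
}

#' Attribute a peak to the latest preceding stimulus event
#'
#' The stimulus has two events: onset (t = 0) and offset
#' (t = stimulus duration). A peak is attributed to the latest event that
#' precedes it.
#'
#' @param peak_time seconds.
#' @param stimulus_duration seconds.
#' @return list with \code{event} ("onset"/"offset"/NA) and \code{event_time}.
#' @export
attribute_event <- function(peak_time, stimulus_duration = 8) {
  if (peak_time < 0) return(list(event = NA_character_, event_time = NA_real_))
  if (peak_time < stimulus_duration)
    list(event = "onset", event_time = 0)
  else
    list(event = "offset", event_time = stimulus_duration)
}
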