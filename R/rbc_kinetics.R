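# Erythrocyte particle-tracking velocimetry. Per frame: intensity threshold ->
# connected components -> intensity-weighted centroids; centroids are linked
# into tracks by greedy mutual nearest neighbour with a distance gate; speed
# follows  v (um/s) = fps * scale * sqrt(Disp_x^2 + Disp_y^2)  per track step.

#' Segment erythrocytes in every frame
#'
#' Each frame is optionally median-filtered (3x3), thresholded, and reduced to
#' intensity-weighted centroids of connected components whose area lies in
#' \code{[min_area, max_area]}.
#'
#' @param movie an \code{nvc_movie}.
#' @param channel channel name (default first channel).
#' @param threshold if < 1, a fraction of the 99.9th-percentile frame
#'   intensity (robust to brightness drift); otherwise an absolute intensity.
#' @param min_area,max_area component area bounds in px^2.
#' @param median_filter apply a 3x3 median pre-filter.
#' @return a \code{centroid_set}: list with \code{per_frame} (one data.frame of
#'   \code{y, x, area} per frame; 0-based pixel coordinates) and frame count.
#' @export
segment_rbcs <- function(movie, channel = names(movie$frames)[1],
                         threshold = 0.5, min_area = 2, max_area = 200,
                         median_filter = TRUE) {
  stopifnot(threshold > 0)
  if (!channel %in% names(movie$frames)) stop("no channel named ", channel)
  arr <- movie$frames[[channel]]
  nt <- dim(arr)[1]
  per_frame <- vector("list", nt)
  n_sat <- 0L
  for (f in seq_len(nt)) {
    fr <- arr[f, , ]
    if (median_filter) fr <- median3x3(fr)
    thr <- if (threshold < 1)
      threshold * quantile(fr, 0.999, names = FALSE) else threshold
    bw <- fr > thr
    if (all(bw)) n_sat <- n_sat + 1L
    if (!any(bw)) {
      per_frame[[f]] <- data.frame(y = numeric(0), x = numeric(0),
                                   area = numeric(0))
      next
    }
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw) * 1)))
    lab <- t(lab)                      # back to (y, x)
    labv <- as.integer(lab)
    keep <- labv > 0L
    labv <- labv[keep]
    w <- as.numeric(fr)[keep]
    ys <- row(fr)[keep] - 1; xs <- col(fr)[keep] - 1
    area <- tabulate(labv)
    wsum <- rowsum(w, labv)[, 1]
    cy <- rowsum(w * ys, labv)[, 1] / wsum
    cx <- rowsum(w * xs, labv)[, 1] / wsum
    ok <- area >= min_area & area <= max_area
    per_frame[[f]] <- data.frame(y = cy[ok], x = cx[ok], area = area[ok])
  }
  if (n_sat > 0) warning(n_sat, " frame(s) fully saturated after thresholding")
  structure(list(per_frame = per_frame, n_frames = nt),
            class = "centroid_set")
}

# greedy mutual nearest neighbour between two point sets within a gate;
# ties broken by (distance, row index of a, row index of b)
.mutual_nn_pairs <- function(a, b, gate) {
  if (!nrow(a) || !nrow(b)) return(cbind(i = integer(0), j = integer(0)))
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  d[d > gate^2] <- Inf
  pairs <- NULL
  repeat {
    if (!any(is.finite(d))) break
    # nearest-b for each a and nearest-a for each b; mutual pairs only
    na <- apply(d, 1, which.min)
    nb <- apply(d, 2, which.min)
    mut <- which(nb[na] == seq_len(nrow(d)) &
                 is.finite(d[cbind(seq_len(nrow(d)), na)]))
    if (!length(mut)) {
      # no mutual pair among the remaining: fall back to the global minimum
      ij <- which(d == min(d), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
      mut <- ij[1]; na[ij[1]] <- ij[2]
    }
    for (i in sort(mut)) {
      j <- na[i]
      if (is.finite(d[i, j])) {
        pairs <- rbind(pairs, c(i, j))
        d[i, ] <- Inf; d[, j] <- Inf
      }
    }
  }
  if (is.null(pairs)) return(cbind(i = integer(0), j = integer(0)))
  colnames(pairs) <- c("i", "j")
  pairs
}

#' Link per-frame centroids into trajectories
#'
#' Greedy mutual-nearest-neighbour assignment between the heads of open tracks
#' and the next frame's centroids. Links longer than \code{max_disp} pixels are
#' forbidden; a track may bridge up to \code{max_gap} missing frames (the same
#' gate applies to the whole bridged link), with skipped positions filled by
#' linear interpolation and flagged as inferred.
#'
#' @param cs a \code{centroid_set}.
#' @param max_disp gate in px/frame (> 0). The default 20 px/frame corresponds
#'   to ~390 um/s at 32 fps and 0.609 um/px; match it to the fastest expected
#'   flow.
#' @param max_gap frames a track may skip before it is closed.
#' @return a \code{track_set}: list of data.frames with columns
#'   \code{frame} (1-based), \code{y}, \code{x} (0-based px), \code{inferred}.
#' @export
link_tracks <- function(cs, max_disp = 20, max_gap = 2) {
  stopifnot(max_disp > 0, max_gap >= 0)
  # tracks held as growing parallel vectors (frame, y, x, inferred)
  tr_frame <- list(); tr_y <- list(); tr_x <- list(); tr_inf <- list()
  open_id <- integer(0)
  head_y <- head_x <- numeric(0); head_f <- integer(0)
  for (f in seq_len(cs$n_frames)) {
    det <- cs$per_frame[[f]]
    dy <- det$y; dx <- det$x
    # order detections lexicographically for deterministic tie-breaks
    if (length(dy)) { o <- order(dy, dx); dy <- dy[o]; dx <- dx[o] }
    if (length(open_id)) {
      alive <- (f - head_f) <= max_gap + 1L
      open_id <- open_id[alive]
      head_y <- head_y[alive]; head_x <- head_x[alive]; head_f <- head_f[alive]
      if (length(open_id) && length(dy)) {
        # strict gate: total link length never exceeds max_disp
        pr <- .mutual_nn_pairs(cbind(head_y, head_x), cbind(dy, dx),
                               gate = max_disp)
        used_det <- rep(FALSE, length(dy))
        for (r in seq_len(nrow(pr))) {
          hi <- pr[r, 1]; j <- pr[r, 2]
          k <- open_id[hi]
          g <- f - head_f[hi]
          if (g > 1L) {             # bridge the gap by linear interpolation
            ff <- (head_f[hi] + 1L):(f - 1L)
            w <- (ff - head_f[hi]) / g
            tr_frame[[k]] <- c(tr_frame[[k]], ff)
            tr_y[[k]] <- c(tr_y[[k]], head_y[hi] + w * (dy[j] - head_y[hi]))
            tr_x[[k]] <- c(tr_x[[k]], head_x[hi] + w * (dx[j] - head_x[hi]))
            tr_inf[[k]] <- c(tr_inf[[k]], rep(TRUE, length(ff)))
          }
          tr_frame[[k]] <- c(tr_frame[[k]], f)
          tr_y[[k]] <- c(tr_y[[k]], dy[j])
          tr_x[[k]] <- c(tr_x[[k]], dx[j])
          tr_inf[[k]] <- c(tr_inf[[k]], FALSE)
          head_y[hi] <- dy[j]; head_x[hi] <- dx[j]; head_f[hi] <- f
          used_det[j] <- TRUE
        }
        if (any(used_det)) { dy <- dy[!used_det]; dx <- dx[!used_det] }
      }
    }
    # unmatched detections start new tracks
    for (j in seq_along(dy)) {
      k <- length(tr_frame) + 1L
      tr_frame[[k]] <- f; tr_y[[k]] <- dy[j]; tr_x[[k]] <- dx[j]
      tr_inf[[k]] <- FALSE
      open_id <- c(open_id, k)
      head_y <- c(head_y, dy[j]); head_x <- c(head_x, dx[j])
      head_f <- c(head_f, f)
    }
  }
  tracks <- lapply(seq_along(tr_frame), function(k)
    data.frame(frame = tr_frame[[k]], y = tr_y[[k]], x = tr_x[[k]],
               inferred = tr_inf[[k]]))
  structure(list(tracks = tracks, n_frames = cs$n_frames), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  len <- vapply(x$tracks, nrow, 1L)
  cat(sprintf("<track_set> %d track(s) over %d frames; lengths %s\n",
              length(x$tracks), x$n_frames,
              if (length(len)) paste(range(len), collapse = "-") else "-"))
  invisible(x)
}

#' Convert tracks to an RBC speed trace
#'
#' Per track step, speed (um/s) = fps * pixel_size * sqrt(Disp_x^2 + Disp_y^2).
#' The raw trace \code{v_raw(t)} is the unweighted mean over all track steps
#' landing in frame t; frames with no steps are NA (missing).
#'
#' @param ts a \code{track_set}.
#' @param fps,pixel_size acquisition constants from the movie metadata.
#' @param movie optional \code{nvc_movie} supplying fps, pixel_size and the
#'   time axis; overrides the two scalars.
#' @param vessel_mask optional logical \code{(y, x)} matrix restricting the
#'   pooled mean to track steps landing inside one vessel (per-vessel pooling
#'   instead of the default whole-field pooling).
#' @return a \code{speed_trace}: data.frame-backed list with \code{t} (s),
#'   \code{v_raw}, \code{v_smooth} (NA until \code{\link{smooth_speed}}),
#'   \code{n_steps}, plus \code{fps}.
#' @export
compute_speed <- function(ts, fps = 32, pixel_size = 0.609, movie = NULL,
                          vessel_mask = NULL) {
  if (!is.null(movie)) { fps <- movie$fps; pixel_size <- movie$pixel_size }
  nt <- ts$n_frames
  vsum <- numeric(nt); nstep <- integer(nt)
  for (tr in ts$tracks) {
    if (nrow(tr) < 2L) next
    if (!is.null(vessel_mask)) {
      ri <- pmin(pmax(round(tr$y) + 1L, 1L), nrow(vessel_mask))
      ci <- pmin(pmax(round(tr$x) + 1L, 1L), ncol(vessel_mask))
      inside <- vessel_mask[cbind(ri, ci)]
    }
    dy <- diff(tr$y); dx <- diff(tr$x)
    v <- fps * pixel_size * sqrt(dx^2 + dy^2)
    fidx <- tr$frame[-1L]
    if (!is.null(vessel_mask)) {
      keep <- inside[-1L]
      v <- v[keep]; fidx <- fidx[keep]
    }
    for (s in seq_along(v)) {
      vsum[fidx[s]] <- vsum[fidx[s]] + v[s]
      nstep[fidx[s]] <- nstep[fidx[s]] + 1L
    }
  }
  v_raw <- ifelse(nstep > 0L, vsum / pmax(nstep, 1L), NA_real_)
  if (all(is.na(v_raw))) warning("no track steps: speed trace is all-missing")
  t_rel <- (seq_len(nt) - 1) / fps
  structure(list(t = t_rel, v_raw = v_raw, v_smooth = rep(NA_real_, nt),
                 n_steps = nstep, fps = fps, pixel_size = pixel_size),
            class = "speed_trace")
}

#' Attach the experiment time axis to a speed trace
#' @param st a \code{speed_trace}.
#' @param movie the source \code{nvc_movie} (for stimulus onset).
#' @return the trace with \code{t} relative to stimulus onset.
#' @export
align_trace <- function(st, movie) {
  st$t <- frame_times(movie)
  st
}

#' Interpolate gaps and smooth an RBC speed trace
#'
#' Missing frames are filled by linear interpolation between the nearest
#' observed neighbours (gaps longer than \code{max_interp_gap_s} are left
#' missing), then a centred moving average of \code{round(bin_s * fps)} frames
#' (forced odd) is applied; window edges use shrinking windows.
#'
#' @param st a \code{speed_trace}.
#' @param bin_s moving-average bin in seconds (default 3).
#' @param max_interp_gap_s longest gap (s) bridged by interpolation.
#' @return the trace with \code{v_smooth} filled.
#' @export
smooth_speed <- function(st, bin_s = 3, max_interp_gap_s = 1) {
  stopifnot(bin_s > 0)
  v <- st$v_raw
  if (all(is.na(v))) stop("cannot smooth an all-missing speed trace")
  filled <- .interp_gaps(v, max_gap = round(max_interp_gap_s * st$fps))
  w <- as.integer(round(bin_s * st$fps))
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(w, 1L)
  st$v_smooth <- zoo::rollapply(filled, width = w,
                                FUN = function(z) if (all(is.na(z))) NA_real_
                                                  else mean(z, na.rm = TRUE),
                                partial = TRUE, align = "center")
  st
}

# linear interpolation of NA runs no longer than max_gap samples
.interp_gaps <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  obs <- which(!is.na(v))
  if (length(obs) < 2L) return(v)
  out <- v
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == length(v)) next            # leading/trailing gaps stay
    if (r$lengths[k] > max_gap) next
    out[s:e] <- approx(x = c(s - 1L, e + 1L), y = v[c(s - 1L, e + 1L)],
                       xout = s:e)$y
  }
  out
}

#' Stimulus-locked change in RBC speed
#'
#' delta = mean smoothed speed over the response window minus the mean over
#' the baseline window; per-period means are returned for the period-wise
#' statistics.
#'
#' @param st a smoothed, aligned \code{speed_trace}.
#' @param windows an \code{nvc_periods}.
#' @return list with \code{delta_um_s} and \code{period_means} (named numeric:
#'   baseline, response, recovery).
#' @export
delta_rbc_speed <- function(st, windows) {
  if (all(is.na(st$v_smooth))) stop("trace has no smoothed values; run smooth_speed()")
  means <- vapply(period_names, function(p) {
    sel <- in_window(st$t, windows[[p]]) & !is.na(st$v_smooth)
    if (!any(sel)) stop("no covered frames in the ", p, " window")
    mean(st$v_smooth[sel])
  }, numeric(1))
  list(delta_um_s = means[["response"]] - means[["baseline"]],
       period_means = means)
}
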