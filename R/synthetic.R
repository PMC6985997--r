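# Synthetic imagery with analytic ground truth. The generators emulate the
# statistical structure the analysis assumes: bright moving blobs confined to
# tubular lumina whose speed steps up during the stimulus window, a diffuse
# tectal calcium channel with onset/offset transients, and 3-D tubular vessel
# trees with known topology and radii. All randomness is seeded and the seed is
# recorded in the truth sidecar, so a rerun reproduces the imagery bit-for-bit.

#' Specify a synthetic vessel tree
#'
#' @param segments data.frame with columns \code{x0, y0, z0, x1, y1, z1}
#'   (endpoint coordinates, micrometres) and \code{radius} (micrometres).
#'   Branch topology is implied by shared endpoints. For planar trees set
#'   z to 0.
#' @param background_intensity,vessel_intensity mean photon counts outside /
#'   inside the lumen (a.u., >= 0).
#' @param noise_sd additive Gaussian camera noise s.d.
#' @return a \code{vessel_tree_spec} object.
#' @export
vessel_tree_spec <- function(segments, background_intensity = 10,
                             vessel_intensity = 200, noise_sd = 0) {
  need <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius")
  if (!all(need %in% names(segments))) {
    if (all(c("x0", "y0", "x1", "y1", "radius") %in% names(segments))) {
      segments$z0 <- segments$z0 %||% 0
      segments$z1 <- segments$z1 %||% 0
    } else stop("segments must have columns x0,y0,[z0],x1,y1,[z1],radius")
  }
  if (nrow(segments) < 1L) stop("at least one segment required")
  if (any(segments$radius <= 0)) stop("radii must be > 0")
  if (background_intensity < 0 || vessel_intensity < 0)
    stop("intensities must be >= 0")
  len <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2 +
              (segments$z1 - segments$z0)^2)
  if (any(len == 0)) stop("zero-length segment")
  structure(list(segments = segments, length = len,
                 background_intensity = background_intensity,
                 vessel_intensity = vessel_intensity, noise_sd = noise_sd),
            class = "vessel_tree_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic ground truth of a tree spec
#'
#' Branch points are distinct endpoint locations where >= 3 segments meet
#' (coordinates matched to 1e-6 um). Total length is the sum of segment
#' lengths.
#'
#' @param spec a \code{vessel_tree_spec}.
#' @return list with \code{branch_point_count}, \code{total_length_um},
#'   \code{segment_lengths_um}, \code{radii_um}.
#' @export
tree_truth <- function(spec) {
  s <- spec$segments
  ends <- rbind(as.matrix(s[, c("x0", "y0", "z0")]),
                as.matrix(s[, c("x1", "y1", "z1")]))
  key <- apply(round(ends * 1e6), 1, paste, collapse = ",")
  mult <- table(key)
  list(branch_point_count = sum(mult >= 3),
       total_length_um = sum(spec$length),
       segment_lengths_um = spec$length,
       radii_um = s$radius)
}

# squared distance from points (n x 3 matrix) to a segment a-b
.dist2_to_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
        (p[, 3] - a[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  (p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2 +
    (p[, 3] - (a[3] + t * ab[3]))^2
}

#' Render a vessel tree as a 3-D stack with known geometry
#'
#' Voxels whose centre lies within \code{radius} of any segment axis receive
#' \code{vessel_intensity}; all voxels receive \code{background_intensity} plus
#' clipped Gaussian noise. Voxel centres sit at 0-based index times pitch.
#'
#' @param spec a \code{vessel_tree_spec} (micrometre coordinates).
#' @param dim_zyx integer stack shape \code{(z, y, x)}.
#' @param voxel_size \code{(z, y, x)} micrometre pitch.
#' @param seed integer RNG seed for the noise.
#' @return list with \code{stack} (an \code{nvc_zstack}, channel \code{kdrl}),
#'   \code{mask} (true lumen support) and \code{truth} (see
#'   \code{\link{tree_truth}}, plus the seed).
#' @export
make_vessel_stack <- function(spec, dim_zyx = c(60, 128, 128),
                              voxel_size = c(1, 1, 1), seed = 1) {
  s <- spec$segments
  lim <- (dim_zyx - 1) * voxel_size   # extent in um, (z, y, x)
  bad <- s$x0 - s$radius < 0 | s$x1 - s$radius < 0 |
    s$y0 - s$radius < 0 | s$y1 - s$radius < 0 |
    s$z0 - s$radius < 0 | s$z1 - s$radius < 0 |
    s$x0 + s$radius > lim[3] | s$x1 + s$radius > lim[3] |
    s$y0 + s$radius > lim[2] | s$y1 + s$radius > lim[2] |
    s$z0 + s$radius > lim[1] | s$z1 + s$radius > lim[1]
  if (any(bad)) stop("tube(s) ", paste(which(bad), collapse = ", "),
                     " extend outside the volume bounds")
  mask <- array(FALSE, dim_zyx)
  zc <- (seq_len(dim_zyx[1]) - 1) * voxel_size[1]
  yc <- (seq_len(dim_zyx[2]) - 1) * voxel_size[2]
  xc <- (seq_len(dim_zyx[3]) - 1) * voxel_size[3]
  for (i in seq_len(nrow(s))) {
    a <- c(s$x0[i], s$y0[i], s$z0[i]); b <- c(s$x1[i], s$y1[i], s$z1[i])
    r <- s$radius[i]
    zi <- which(zc >= min(a[3], b[3]) - r - 1 & zc <= max(a[3], b[3]) + r + 1)
    yi <- which(yc >= min(a[2], b[2]) - r - 1 & yc <= max(a[2], b[2]) + r + 1)
    xi <- which(xc >= min(a[1], b[1]) - r - 1 & xc <= max(a[1], b[1]) + r + 1)
    if (!length(zi) || !length(yi) || !length(xi)) next
    g <- expand.grid(x = xc[xi], y = yc[yi], z = zc[zi])
    d2 <- .dist2_to_segment(as.matrix(g), a, b)
    inside <- array(d2 <= r^2, c(length(xi), length(yi), length(zi)))
    # reorder (x,y,z) -> (z,y,x)
    mask[zi, yi, xi] <- mask[zi, yi, xi] | aperm(inside, c(3, 2, 1))
  }
  set.seed(seed)
  vox <- spec$background_intensity +
    (spec$vessel_intensity - spec$background_intensity) * mask
  if (spec$noise_sd > 0)
    vox <- pmax(vox + rnorm(length(vox), 0, spec$noise_sd), 0)
  tr <- tree_truth(spec)
  tr$seed <- seed
  list(stack = z_stack(list(kdrl = vox), voxel_size), mask = mask, truth = tr)
}

# project a tree spec to the imaging plane and rasterise its lumen mask (y, x)
render_tree_mask2d <- function(spec, shape_yx, pixel_size) {
  s <- spec$segments
  mask <- matrix(FALSE, shape_yx[1], shape_yx[2])
  yc <- (seq_len(shape_yx[1]) - 1) * pixel_size
  xc <- (seq_len(shape_yx[2]) - 1) * pixel_size
  for (i in seq_len(nrow(s))) {
    a <- c(s$x0[i], s$y0[i], 0); b <- c(s$x1[i], s$y1[i], 0)
    r <- s$radius[i]
    yi <- which(yc >= min(a[2], b[2]) - r - 1 & yc <= max(a[2], b[2]) + r + 1)
    xi <- which(xc >= min(a[1], b[1]) - r - 1 & xc <= max(a[1], b[1]) + r + 1)
    if (!length(yi) || !length(xi)) next
    g <- cbind(rep(xc[xi], times = length(yi)),
               rep(yc[yi], each = length(xi)), 0)
    d2 <- .dist2_to_segment(g, a, b)
    mask[yi, xi] <- mask[yi, xi] |
      t(matrix(d2 <= r^2, length(xi), length(yi)))
  }
  mask
}

#' Simulate an erythrocyte-channel movie with stepped flow speed
#'
#' Particles are isotropic Gaussian blobs advected along the 2-D tree
#' centrelines at \code{v_base} during baseline/recovery and \code{v_resp}
#' during the response window; a particle reaching the end of its segment
#' wraps to the segment start. Cells are placed at jittered equal arc spacing
#' along the tree so that the default tracker gate resolves them.
#'
#' Cells are assigned round-robin to segments and equally spaced on each
#' segment's ring with one global phase, which keeps concurrent detections
#' well separated at every frame (the tracker-solvability condition the
#' defaults are chosen for).
#'
#' @param tree2d a \code{vessel_tree_spec} with planar (z = 0) segments,
#'   micrometre coordinates.
#' @param v_base,v_resp speeds in micrometres per second (>= 0).
#' @param n_cells number of erythrocytes (>= 1).
#' @param windows an \code{nvc_periods} object.
#' @param fps frames per second.
#' @param pixel_size micrometres per pixel.
#' @param shape_yx frame shape in pixels.
#' @param noise_sd additive Gaussian noise s.d. (counts).
#' @param blob_sigma blob s.d. in pixels.
#' @param blob_amplitude blob peak amplitude above background (counts).
#' @param vessel_glow lumen fluorescence above background (counts).
#' @param pad_s extra seconds simulated before the baseline window and after
#'   the recovery window.
#' @param seed RNG seed.
#' @return list with \code{movie} (channel \code{gata1}) and \code{truth}:
#'   \code{v_profile} (true speed per frame), \code{delta_speed_um_s}
#'   (response-mean minus baseline-mean of the profile), per-frame 0-based
#'   particle positions \code{pos_yx_px} (array \code{[t, cell, 2]}),
#'   and the seed.
#' @export
simulate_rbc_movie <- function(tree2d, v_base = 300, v_resp = 300,
                               n_cells = 10, windows = define_periods(),
                               fps = 32, pixel_size = 0.609,
                               shape_yx = c(128, 208), noise_sd = 2,
                               blob_sigma = 1.5, blob_amplitude = 400,
                               vessel_glow = 15, pad_s = 1, seed = 1) {
  stopifnot(v_base >= 0, v_resp >= 0, n_cells >= 1)
  seg <- tree2d$segments
  if (any(tree2d$segments$radius / pixel_size <= blob_sigma))
    warning("blob sigma >= vessel radius in pixels; segmentation may merge cells")
  t0 <- windows$baseline[1] - pad_s
  t1 <- windows$recovery[2] + pad_s
  nt <- as.integer(round((t1 - t0) * fps))
  tt <- t0 + (seq_len(nt) - 1) / fps
  v_profile <- ifelse(in_window(tt, windows$response), v_resp, v_base)

  set.seed(seed)
  # round-robin assignment to segments; equal ring spacing per segment with
  # one global phase so cells stay maximally separated at all times
  nseg <- nrow(seg)
  seg_id <- (seq_len(n_cells) - 1L) %% nseg + 1L
  phase <- runif(1)
  s_on_seg <- numeric(n_cells)
  for (i in unique(seg_id)) {
    cells_i <- which(seg_id == i)
    k <- length(cells_i)
    s_on_seg[cells_i] <- (phase + (seq_len(k) - 1) / k) %% 1 * tree2d$length[i]
  }

  mask <- render_tree_mask2d(tree2d, shape_yx, pixel_size)
  base_frame <- matrix(tree2d$background_intensity, shape_yx[1], shape_yx[2]) +
    vessel_glow * mask

  pos <- array(NA_real_, c(nt, n_cells, 2))
  ux <- (seg$x1 - seg$x0) / tree2d$length
  uy <- (seg$y1 - seg$y0) / tree2d$length
  # rendered (y, x, t) for contiguous per-frame writes, permuted once at the end
  frames <- array(0, c(shape_yx[1], shape_yx[2], nt))
  half <- ceiling(4 * blob_sigma)
  for (f in seq_len(nt)) {
    img <- base_frame
    for (k in seq_len(n_cells)) {
      i <- seg_id[k]
      s <- s_on_seg[k] %% tree2d$length[i]
      x_um <- seg$x0[i] + s * ux[i]
      y_um <- seg$y0[i] + s * uy[i]
      px <- x_um / pixel_size; py <- y_um / pixel_size   # 0-based
      pos[f, k, ] <- c(py, px)
      r0 <- max(1L, floor(py) - half + 1L); r1 <- min(shape_yx[1], floor(py) + half + 1L)
      c0 <- max(1L, floor(px) - half + 1L); c1 <- min(shape_yx[2], floor(px) + half + 1L)
      if (r0 > r1 || c0 > c1) next
      yy <- (r0:r1) - 1; xx <- (c0:c1) - 1
      g <- blob_amplitude *
        outer(exp(-(yy - py)^2 / (2 * blob_sigma^2)),
              exp(-(xx - px)^2 / (2 * blob_sigma^2)))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
      s_on_seg[k] <- s_on_seg[k] + v_profile[f] / fps
    }
    frames[, , f] <- img
  }
  if (noise_sd > 0)
    frames <- pmax(frames + rnorm(length(frames), 0, noise_sd), 0)
  frames <- round(pmin(frames, 65535))
  frames <- aperm(frames, c(3, 1, 2))
  movie <- time_series_movie(list(gata1 = frames), fps = fps,
                             pixel_size = pixel_size,
                             stimulus_onset = -t0,
                             stimulus_duration = windows$stimulus_duration %||% 8)
  truth <- list(
    v_base = v_base, v_resp = v_resp,
    v_profile = v_profile, t = tt,
    delta_speed_um_s = mean(v_profile[in_window(tt, windows$response)]) -
      mean(v_profile[in_window(tt, windows$baseline)]),
    pos_yx_px = pos, seed = seed, n_cells = n_cells)
  list(movie = movie, truth = truth)
}

#' Double-exponential calcium transient kernel
#'
#' \code{k(t) = (1 - exp(-t / rise)) * exp(-t / decay)} for t >= 0, else 0.
#'
#' @param t seconds since the event.
#' @param rise,decay kinetic time constants (seconds).
#' @return kernel values.
#' @export
calcium_kernel <- function(t, rise = 0.2, decay = 1.5) {
  ifelse(t < 0, 0, (1 - exp(-t / rise)) * exp(-t / decay))
}

#' Peak time and value of the calcium kernel
#' @param rise,decay kinetic time constants (seconds).
#' @return list with \code{t_peak} and \code{k_max}.
#' @export
calcium_kernel_peak <- function(rise = 0.2, decay = 1.5) {
  t_peak <- rise * log(1 + decay / rise)
  list(t_peak = t_peak, k_max = calcium_kernel(t_peak, rise, decay))
}

#' Specify ground truth for a synthetic calcium recording
#'
#' @param event_times seconds (relative to stimulus onset) of calcium events.
#' @param amplitudes peak dF/F amplitudes (> 0), recycled to the events.
#' @param rise,decay kinetic time constants in seconds.
#' @param f0 tectal baseline fluorescence above background (counts).
#' @return a \code{calcium_truth} list.
#' @export
calcium_truth <- function(event_times, amplitudes = 0.5, rise = 0.2,
                          decay = 1.5, f0 = 400) {
  if (length(event_times)) stopifnot(all(rep_len(amplitudes, length(event_times)) > 0))
  list(event_times = event_times,
       amplitudes = rep_len(amplitudes, length(event_times)),
       rise = rise, decay = decay, f0 = f0)
}

#' Simulate a tectal calcium-channel movie
#'
#' The tectal region holds \code{background_level + f0 * (1 + s(t))} where
#' \code{s(t)} is the sum of amplitude-scaled transient kernels (each scaled so
#' its own maximum equals the stated amplitude); all other pixels hold
#' \code{background_level}. With this additive-background model the noiseless
#' dF/F of the recording equals \code{s(t)} exactly.
#'
#' @param truth a \code{calcium_truth}.
#' @param windows an \code{nvc_periods}.
#' @param fps frames per second.
#' @param shape_yx frame shape (pixels).
#' @param background_level camera background (counts).
#' @param noise_sd additive Gaussian noise s.d.
#' @param pad_s seconds simulated beyond the windows on each side.
#' @param seed RNG seed.
#' @return list with \code{movie} (channel \code{gcamp}), \code{tectum_roi} and
#'   \code{background_roi} logical masks, and \code{truth} augmented with the
#'   seed and the noiseless \code{dff_true} trace.
#' @export
simulate_calcium_movie <- function(truth, windows = define_periods(), fps = 32,
                                   shape_yx = c(48, 80), background_level = 50,
                                   noise_sd = 0, pad_s = 1, seed = 1) {
  t0 <- windows$baseline[1] - pad_s
  t1 <- windows$recovery[2] + pad_s
  nt <- as.integer(round((t1 - t0) * fps))
  tt <- t0 + (seq_len(nt) - 1) / fps
  s_t <- rep(0, nt)
  if (length(truth$event_times)) {
    kmax <- calcium_kernel_peak(truth$rise, truth$decay)$k_max
    for (j in seq_along(truth$event_times))
      s_t <- s_t + truth$amplitudes[j] / kmax *
        calcium_kernel(tt - truth$event_times[j], truth$rise, truth$decay)
  }
  ny <- shape_yx[1]; nx <- shape_yx[2]
  tectum <- matrix(FALSE, ny, nx)
  tectum[, seq_len(floor(nx * 0.45))] <- TRUE
  background <- matrix(FALSE, ny, nx)
  background[, (nx - floor(nx * 0.25) + 1):nx] <- TRUE
  set.seed(seed)
  frames <- array(background_level, c(ny, nx, nt))
  tec_idx <- which(tectum)
  npix <- ny * nx
  for (f in seq_len(nt))
    frames[(f - 1L) * npix + tec_idx] <- background_level +
      truth$f0 * (1 + s_t[f])
  if (noise_sd > 0)
    frames <- pmax(frames + rnorm(length(frames), 0, noise_sd), 0)
  frames <- aperm(frames, c(3, 1, 2))
  movie <- time_series_movie(list(gcamp = frames), fps = fps, pixel_size = 1,
                             stimulus_onset = -t0,
                             stimulus_duration = windows$stimulus_duration %||% 8)
  truth$seed <- seed
  truth$dff_true <- s_t
  truth$t <- tt
  list(movie = movie, tectum_roi = tectum, background_roi = background,
       truth = truth)
}
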