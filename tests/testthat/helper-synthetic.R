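# Shared fixtures: everything is generated in code at test time.

# short acquisition for fast end-to-end tests: 16 fps, 4/6/4 s windows
short_cfg <- function(seed = 7) {
  cfg <- default_config()
  cfg$fps <- 16
  cfg$stimulus_onset <- 5; cfg$stimulus_duration <- 3
  cfg$baseline_len <- 4; cfg$response_len <- 6; cfg$recovery_len <- 4
  cfg$rbc$max_disp <- 45
  cfg$seed <- seed
  cfg
}

short_windows <- function() define_periods(5, 3, 4, 6, 4)

# standard full-length study windows (10/20/10 s around an 8 s stimulus)
study_windows <- function() define_periods(29, 8, 10, 20, 10)

# small planar tree for flow movies at reduced frame size: 4 vessels, one
# ring per vessel
small_flow_tree <- function(pixel_size = 0.609) {
  y <- c(12, 24, 36, 48) * pixel_size
  vessel_tree_spec(data.frame(
    x0 = 6 * pixel_size, y0 = y, x1 = 201 * pixel_size, y1 = y,
    z0 = 0, z1 = 0, radius = 2.4),
    background_intensity = 10, vessel_intensity = 10, noise_sd = 0)
}

# a centroid_set built directly from a list of per-frame (y, x) matrices
centroids_from_list <- function(frames) {
  per_frame <- lapply(frames, function(m) {
    m <- matrix(m, ncol = 2)
    data.frame(y = m[, 1], x = m[, 2], area = rep(9, nrow(m)))
  })
  structure(list(per_frame = per_frame, n_frames = length(per_frame)),
            class = "centroid_set")
}

# exhaustive minimum-total-displacement frame-to-frame assignment (oracle for
# the greedy tracker; enumerates all injective assignments within the gate)
oracle_links <- function(a, b, gate) {
  a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(cbind(i = integer(0), j = integer(0)))
  d <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  ok <- d <= gate^2
  best <- NULL; best_cost <- Inf; best_n <- -1L
  subsets_a <- unlist(lapply(0:na, function(k)
    utils::combn(seq_len(na), k, simplify = FALSE)), recursive = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (sa in subsets_a) {
    k <- length(sa)
    if (k > nb) next
    for (sb in utils::combn(seq_len(nb), k, simplify = FALSE))
      for (p in perms(sb)) {
        if (k > 0L && any(!ok[cbind(sa, p)])) next
        cost <- if (k > 0L) sum(sqrt(d[cbind(sa, p)])) else 0
        # maximise matches first, then minimise total displacement
        if (k > best_n || (k == best_n && cost < best_cost - 1e-12)) {
          best <- if (k > 0L) cbind(i = sa, j = p) else
            cbind(i = integer(0), j = integer(0))
          best_cost <- cost; best_n <- k
        }
      }
  }
  best[order(best[, 1]), , drop = FALSE]
}

# links chosen by link_tracks between two consecutive frames (no gaps)
greedy_links <- function(a, b, gate) {
  cs <- centroids_from_list(list(a, b))
  ts <- link_tracks(cs, max_disp = gate, max_gap = 0)
  out <- NULL
  a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
  for (tr in ts$tracks) {
    if (nrow(tr) == 2L) {
      i <- which(abs(a[, 1] - tr$y[1]) < 1e-9 & abs(a[, 2] - tr$x[1]) < 1e-9)
      j <- which(abs(b[, 1] - tr$y[2]) < 1e-9 & abs(b[, 2] - tr$x[2]) < 1e-9)
      out <- rbind(out, cbind(i = i, j = j))
    }
  }
  if (is.null(out)) return(cbind(i = integer(0), j = integer(0)))
  out[order(out[, 1]), , drop = FALSE]
}
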