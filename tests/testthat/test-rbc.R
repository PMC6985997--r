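test_that("segmentation recovers isolated blob centroids", {
  # three separated Gaussian blobs on a quiet background
  frame <- matrix(10, 60, 80)
  truth <- rbind(c(15.3, 20.7), c(40.1, 25.4), c(30.6, 60.2))
  for (k in 1:3) {
    yy <- 0:59; xx <- 0:79
    frame <- frame + 400 * outer(exp(-(yy - truth[k, 1])^2 / (2 * 1.5^2)),
                                 exp(-(xx - truth[k, 2])^2 / (2 * 1.5^2)))
  }
  mv <- time_series_movie(array(frame, c(1, 60, 80)), fps = 32,
                          pixel_size = 0.609)
  cs <- segment_rbcs(mv, median_filter = FALSE)
  expect_equal(nrow(cs$per_frame[[1]]), 3L)
  got <- as.matrix(cs$per_frame[[1]][order(cs$per_frame[[1]]$y), c("y", "x")])
  expect_true(all(sqrt(rowSums((got - truth[order(truth[, 1]), ])^2)) < 0.5))

  # blank frame: zero centroids, not an error
  blank <- time_series_movie(array(10, c(1, 20, 20)), fps = 32,
                             pixel_size = 0.609)
  expect_equal(nrow(segment_rbcs(blank, threshold = 100,
                                 median_filter = FALSE)$per_frame[[1]]), 0L)

  # a blob smaller than min_area is rejected
  tiny <- matrix(0, 20, 20); tiny[10, 10] <- 500
  mv2 <- time_series_movie(array(tiny, c(1, 20, 20)), fps = 32,
                           pixel_size = 0.609)
  expect_equal(nrow(segment_rbcs(mv2, threshold = 100, min_area = 4,
                                 median_filter = FALSE)$per_frame[[1]]), 0L)
})

test_that("linking follows single particles and respects the gap rule", {
  # one blob moving +2 px/frame in x
  frames <- lapply(0:9, function(f) c(10, 5 + 2 * f))
  ts <- link_tracks(centroids_from_list(frames), max_disp = 5, max_gap = 2)
  expect_length(ts$tracks, 1L)
  tr <- ts$tracks[[1]]
  expect_equal(diff(tr$x), rep(2, 9))
  expect_equal(diff(tr$y), rep(0, 9))

  # a vanishing particle beyond max_gap starts a new track
  frames2 <- c(lapply(0:3, function(f) c(10, 5 + 2 * f)),
               lapply(1:4, function(f) cbind(numeric(0), numeric(0))),
               lapply(8:10, function(f) c(10, 5 + 2 * f)))
  ts2 <- link_tracks(centroids_from_list(frames2), max_disp = 5, max_gap = 2)
  expect_length(ts2$tracks, 2L)

  # a short gap within max_gap is bridged with inferred positions
  frames3 <- list(c(10, 5), cbind(numeric(0), numeric(0)), c(10, 9))
  ts3 <- link_tracks(centroids_from_list(frames3), max_disp = 5, max_gap = 2)
  expect_length(ts3$tracks, 1L)
  expect_equal(ts3$tracks[[1]]$x, c(5, 7, 9))
  expect_equal(ts3$tracks[[1]]$inferred, c(FALSE, TRUE, FALSE))
})

test_that("greedy links equal the exhaustive minimum-displacement assignment", {
  # scripted battery of noiseless instances with up to 3 particles
  battery <- list(
    list(a = c(10, 10), b = c(10, 14), gate = 6),
    list(a = rbind(c(10, 10), c(30, 10)), b = rbind(c(10, 14), c(30, 14)),
         gate = 6),
    # crossing particles with the gate below the crossing jump: identities
    # follow nearest-neighbour continuity
    list(a = rbind(c(20, 20), c(24, 20)), b = rbind(c(21.5, 23), c(22.5, 23)),
         gate = 4),
    list(a = rbind(c(10, 10), c(20, 20), c(30, 30)),
         b = rbind(c(11, 11), c(21, 21), c(31, 31)), gate = 3),
    # one particle leaves the field: best matching links the remaining two
    list(a = rbind(c(10, 10), c(20, 20), c(30, 30)),
         b = rbind(c(11, 11), c(21, 21)), gate = 3),
    # one particle enters
    list(a = rbind(c(10, 10)), b = rbind(c(11, 11), c(40, 40)), gate = 3))
  set.seed(31)
  for (r in 1:20) {                       # randomised well-separated triples
    n <- sample(1:3, 1)
    a <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    while (n > 1 && min(dist(a)) < 20)
      a <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    b <- a + matrix(runif(2 * n, -4, 4), n, 2)
    battery[[length(battery) + 1L]] <- list(a = a, b = b, gate = 8)
  }
  for (case in battery) {
    expect_identical(greedy_links(case$a, case$b, case$gate),
                     oracle_links(case$a, case$b, case$gate))
  }
})

test_that("speed follows fps * scale * sqrt(dx^2 + dy^2) per track step", {
  mk <- function(disps, fps, ps) {
    frames <- Reduce(function(p, d) p + d, disps,
                     accumulate = TRUE, init = c(20, 20))
    ts <- link_tracks(centroids_from_list(frames), max_disp = 50, max_gap = 0)
    compute_speed(ts, fps = fps, pixel_size = ps)
  }
  # Disp = (0, 1) px at 32 fps and 0.609 um/px -> 19.488 um/s
  st <- mk(replicate(5, c(0, 1), simplify = FALSE), 32, 0.609)
  expect_equal(st$v_raw[-1], rep(32 * 0.609, 5))
  expect_equal(st$v_raw[2], 19.488)
  # stationary particle
  expect_equal(mk(replicate(3, c(0, 0), simplify = FALSE), 32, 0.609)$v_raw[-1],
               rep(0, 3))
  # 3-4-5 triangle at unit constants
  expect_equal(mk(list(c(3, 4)), 1, 1)$v_raw[2], 5)
  # empty track set warns and yields all-missing
  empty <- centroids_from_list(list(cbind(numeric(0), numeric(0)),
                                    cbind(numeric(0), numeric(0))))
  expect_warning(st0 <- compute_speed(link_tracks(empty, 5, 0), 32, 0.609),
                 "all-missing")
  expect_true(all(is.na(st0$v_raw)))
})

test_that("smoothing interpolates gaps and averages with shrinking edges", {
  mkst <- function(v, fps = 10) {
    structure(list(t = (seq_along(v) - 1) / fps, v_raw = v,
                   v_smooth = rep(NA_real_, length(v)),
                   n_steps = as.integer(!is.na(v)), fps = fps,
                   pixel_size = 1),
              class = "speed_trace")
  }
  # constant trace is a fixed point
  st <- smooth_speed(mkst(rep(7, 50)), bin_s = 1)
  expect_equal(st$v_smooth, rep(7, 50))
  # unit impulse -> plateau of height 1/w over the full window
  v <- rep(0, 61); v[31] <- 1
  w <- 11                                  # round(1 s * 10 fps) forced odd
  sm <- smooth_speed(mkst(v), bin_s = 1)
  expect_equal(sm$v_smooth[31], 1 / w)
  expect_equal(sm$v_smooth[31 - 5], 1 / w)
  expect_equal(sm$v_smooth[31 + 6], 0)
  # one missing frame between 10 and 20 is interpolated to 15
  v2 <- c(rep(10, 10), NA, rep(20, 10))
  filled <- nvcflow:::.interp_gaps(v2, max_gap = 10)
  expect_equal(filled[11], 15)
  # gaps longer than the limit stay missing
  v3 <- c(rep(10, 5), rep(NA, 8), rep(20, 5))
  expect_true(all(is.na(nvcflow:::.interp_gaps(v3, max_gap = 3)[6:13])))
  expect_error(smooth_speed(mkst(rep(NA_real_, 10))), "all-missing")
})

test_that("delta RBC speed is the response-minus-baseline window mean", {
  w <- define_periods(10, 3, 4, 6, 4)
  fps <- 10
  t <- seq(-5, 11, by = 1 / fps)
  v <- ifelse(t >= 0 & t < 6, 360, 300)
  st <- structure(list(t = t, v_raw = v, v_smooth = v,
                       n_steps = rep(1L, length(t)), fps = fps,
                       pixel_size = 1),
                  class = "speed_trace")
  d <- delta_rbc_speed(st, w)
  expect_equal(d$delta_um_s, 60)
  expect_equal(unname(d$period_means), c(300, 360, 300))
  # constant speed: delta 0
  st0 <- st; st0$v_smooth <- rep(300, length(t))
  expect_equal(delta_rbc_speed(st0, w)$delta_um_s, 0)
  # empty window errors with its name
  stshort <- st; stshort$v_smooth[t < 0] <- NA
  expect_error(delta_rbc_speed(stshort, w), "baseline")
})

test_that("a vessel mask restricts pooling to one vessel's track steps", {
  # two particles in different image halves moving at different speeds
  frames <- lapply(0:5, function(f) rbind(c(10, 5 + 2 * f), c(40, 5 + 4 * f)))
  ts <- link_tracks(centroids_from_list(frames), max_disp = 6, max_gap = 0)
  mask_top <- matrix(FALSE, 60, 60); mask_top[1:25, ] <- TRUE
  st_all <- compute_speed(ts, fps = 1, pixel_size = 1)
  st_top <- compute_speed(ts, fps = 1, pixel_size = 1,
                          vessel_mask = mask_top)
  expect_equal(st_all$v_raw[-1], rep(3, 5))     # pooled mean of 2 and 4
  expect_equal(st_top$v_raw[-1], rep(2, 5))     # top vessel only
})

test_that("speed estimates are invariant to constant frame translation", {
  w <- short_windows()
  sim <- simulate_rbc_movie(small_flow_tree(), 300, 300, n_cells = 4,
                            windows = w, fps = 16, shape_yx = c(64, 208),
                            noise_sd = 2, seed = 13)
  cs <- segment_rbcs(sim$movie)
  shifted <- cs
  shifted$per_frame <- lapply(cs$per_frame, function(df) {
    df$y <- df$y + 3.25; df$x <- df$x - 1.5; df
  })
  v1 <- compute_speed(link_tracks(cs, 45, 2), fps = 16, pixel_size = 0.609)
  v2 <- compute_speed(link_tracks(shifted, 45, 2), fps = 16,
                      pixel_size = 0.609)
  expect_equal(v1$v_raw, v2$v_raw)
})
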