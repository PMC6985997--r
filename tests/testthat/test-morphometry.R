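
straight_tube <- function(radius = 3.5, noise = 4, seed = 1) {
  spec <- vessel_tree_spec(data.frame(x0 = 14, y0 = 60, z0 = 20, x1 = 114,
                                      y1 = 60, z1 = 20, radius = radius),
                           background_intensity = 10,
                           vessel_intensity = 200, noise_sd = noise)
  make_vessel_stack(spec, dim_zyx = c(40, 128, 128), seed = seed)
}

test_that("Otsu segmentation recovers the true tube support", {
  sim <- straight_tube()
  vm <- segment_vessels(sim$stack)
  m2 <- project_mask(vm)
  truth2 <- apply(sim$mask, c(2, 3), any)
  # agreement within a 1-px boundary band: every disagreeing pixel touches
  # the true boundary
  disagree <- which(m2 != truth2, arr.ind = TRUE)
  if (nrow(disagree)) {
    dmap <- background_distance_map(truth2)
    expect_true(all(dmap[disagree] <= 1.5))
  }
  expect_gt(sum(m2 & truth2) / sum(m2 | truth2), 0.95)

  # constant image: Otsu undefined
  flat <- z_stack(array(7, c(4, 10, 10)), c(1, 1, 1))
  expect_error(segment_vessels(flat), "Otsu")

  # inverted contrast with bright_vessels = FALSE gives the same vessels
  inv <- sim$stack
  inv$voxels$kdrl <- 210 - inv$voxels$kdrl
  vm_inv <- segment_vessels(inv, bright_vessels = FALSE)
  expect_gt(sum(project_mask(vm_inv) & truth2) /
              sum(project_mask(vm_inv) | truth2), 0.95)
})

test_that("skeletonization reproduces tube, Y, and crossing topologies", {
  sim <- straight_tube()
  g <- skeletonize_mip(segment_vessels(sim$stack))
  expect_equal(nrow(g$branch_points), 0L)
  expect_equal(nrow(g$endpoints), 2L)
  expect_length(g$segments, 1L)
  # 1-px-wide skeleton: no pixel retains more than 2 reduced-graph neighbours
  pg <- nvcflow:::.pixel_graph(g$skeleton)
  expect_true(all(igraph::degree(pg$graph) <= 2))

  yspec <- vessel_tree_spec(data.frame(
    x0 = c(20, 64, 64), y0 = c(64, 64, 64), z0 = 20,
    x1 = c(64, 104, 104), y1 = c(64, 30, 98), z1 = 20, radius = 3),
    vessel_intensity = 200, noise_sd = 4)
  ysim <- make_vessel_stack(yspec, dim_zyx = c(40, 128, 128), seed = 2)
  yg <- skeletonize_mip(segment_vessels(ysim$stack))
  expect_equal(nrow(yg$branch_points), 1L)
  expect_equal(nrow(yg$endpoints), 3L)

  # X crossing of two tubes in projection: one clustered 4-way junction
  xspec <- vessel_tree_spec(data.frame(
    x0 = c(24, 24), y0 = c(24, 104), z0 = 20,
    x1 = c(104, 104), y1 = c(104, 24), z1 = 20, radius = 3),
    vessel_intensity = 200, noise_sd = 0)
  xsim <- make_vessel_stack(xspec, dim_zyx = c(40, 128, 128), seed = 3)
  xg <- skeletonize_mip(xsim$mask)
  expect_equal(nrow(xg$branch_points), 1L)
  expect_equal(nrow(xg$endpoints), 4L)

  expect_error(skeletonize_mip(matrix(FALSE, 10, 10)), "empty")
})

test_that("lengths follow the centreline metric on constructed skeletons", {
  # horizontal 1-px line: 100 steps of 1 at 0.609 um/px
  line <- matrix(FALSE, 20, 120)
  line[10, 11:111] <- TRUE
  g <- skeletonize_mip(line)
  len <- measure_lengths(g, pixel_size = 0.609, extend_tips = FALSE,
                         stride = 1)
  expect_equal(len$total_um, 100 * 0.609)

  # 45-degree diagonal of 100 steps: 100 * sqrt(2) * pixel_size
  diag <- matrix(FALSE, 120, 120)
  diag[cbind(11:111, 11:111)] <- TRUE
  gd <- skeletonize_mip(diag)
  lend <- measure_lengths(gd, pixel_size = 0.609, extend_tips = FALSE,
                          stride = 1)
  expect_equal(lend$total_um, 100 * sqrt(2) * 0.609)

  # rendered tubes: recovered total within 5% of analytic truth at any angle
  for (a in c(10, 30, 60)) {
    th <- a * pi / 180
    spec <- vessel_tree_spec(data.frame(
      x0 = 12, y0 = 12, z0 = 20, x1 = 12 + 90 * cos(th),
      y1 = 12 + 90 * sin(th), z1 = 20, radius = 2.5),
      vessel_intensity = 200, noise_sd = 0)
    m <- render_tree_mask2d(spec, c(120, 120), 1)
    lm <- measure_lengths(skeletonize_mip(m), pixel_size = 1)
    expect_lt(abs(lm$total_um - 90) / 90, 0.05)
  }
})

test_that("random trees recover branch points exactly and lengths within 5%", {
  for (s in c(2, 5, 9)) {
    spec <- random_tree_spec(7, seed = s)
    sim <- make_vessel_stack(spec, seed = s)
    g <- skeletonize_mip(segment_vessels(sim$stack))
    expect_equal(nrow(g$branch_points), sim$truth$branch_point_count)
    len <- measure_lengths(g, pixel_size = 1)
    expect_lt(abs(len$total_um - sim$truth$total_length_um) /
                sim$truth$total_length_um, 0.05)
  }
})

test_that("distance transforms equal brute force exactly on small masks", {
  set.seed(5)
  for (r in 1:5) {
    m <- matrix(runif(30 * 30) > 0.45, 30, 30)
    if (!any(m) || all(m)) next
    dt <- background_distance_map(m)
    bg <- which(!m, arr.ind = TRUE)
    for (px in sample(which(m), 40)) {
      ij <- arrayInd(px, dim(m))
      expect_equal(dt[px],
                   sqrt(min((bg[, 1] - ij[1])^2 + (bg[, 2] - ij[2])^2)))
    }
    # edge distance: brute force over the boundary pixel set
    de <- edge_distance_map(m)
    pad <- matrix(FALSE, 32, 32); pad[2:31, 2:31] <- m
    interior <- pad[2:31, 2:31] & pad[1:30, 2:31] & pad[3:32, 2:31] &
      pad[2:31, 1:30] & pad[2:31, 3:32]
    epix <- which(m & !interior, arr.ind = TRUE)
    for (px in sample(seq_len(900), 40)) {
      ij <- arrayInd(px, dim(m))
      expect_equal(de[px],
                   sqrt(min((epix[, 1] - ij[1])^2 + (epix[, 2] - ij[2])^2)))
    }
  }
})

test_that("radii recover tube geometry and compose histograms", {
  # tube of radius 5 px: mean centreline radius within 0.5 px
  spec <- vessel_tree_spec(data.frame(x0 = 14, y0 = 60, z0 = 20, x1 = 114,
                                      y1 = 60, z1 = 20, radius = 5),
                           vessel_intensity = 200, noise_sd = 0)
  sim <- make_vessel_stack(spec, dim_zyx = c(40, 128, 128), seed = 1)
  g <- skeletonize_mip(segment_vessels(sim$stack))
  rad <- measure_radii(g, pixel_size = 1)
  expect_lt(abs(rad$mean_um - 5), 0.5)
  # histogram counts sum to the number of centreline pixels
  expect_equal(sum(rad$histogram$count), sum(g$skeleton))

  # 1-px line mask: minimal vessel, radius below one pixel everywhere
  line <- matrix(FALSE, 20, 60); line[10, 6:55] <- TRUE
  gl <- skeletonize_mip(line)
  rl <- measure_radii(gl, pixel_size = 1)
  expect_true(all(rl$radii_px <= 1))

  # two tubes radius 3 and 6: bimodal histogram with modes at the truths
  two <- vessel_tree_spec(data.frame(
    x0 = c(14, 14), y0 = c(30, 90), z0 = 20, x1 = c(114, 114),
    y1 = c(30, 90), z1 = 20, radius = c(3, 6)),
    vessel_intensity = 200, noise_sd = 0)
  sim2 <- make_vessel_stack(two, dim_zyx = c(40, 128, 128), seed = 2)
  g2 <- skeletonize_mip(segment_vessels(sim2$stack))
  r2 <- measure_radii(g2, pixel_size = 1)
  h <- r2$histogram[order(-r2$histogram$count), ]
  modes <- sort(h$radius_px[1:2])
  expect_lt(abs(modes[1] - 3), 0.75)
  expect_lt(abs(modes[2] - 6), 0.75)
})

test_that("morphometrics are stable under rotations and mask dilation", {
  spec <- random_tree_spec(5, seed = 4)
  sim <- make_vessel_stack(spec, seed = 4)
  m0 <- project_mask(segment_vessels(sim$stack))
  ref <- skeletonize_mip(m0)
  ref_len <- measure_lengths(ref, 1)$total_um
  ref_rad <- measure_radii(ref, pixel_size = 1)$mean_um
  for (rot in 1:3) {
    mr <- m0
    for (k in seq_len(rot)) mr <- t(apply(mr, 2, rev))   # 90-degree turns
    gr <- skeletonize_mip(mr)
    expect_equal(nrow(gr$branch_points), nrow(ref$branch_points))
    expect_lt(abs(measure_lengths(gr, 1)$total_um - ref_len) / ref_len, 0.02)
    expect_lt(abs(measure_radii(gr, pixel_size = 1)$mean_um - ref_rad), 0.1)
  }
  # dilating the mask by 1 px increases every centreline radius by [0, 1.5]
  big <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(m0) * 1), EBImage::makeBrush(3, "diamond")))
  big <- t(big) > 0
  d0 <- edge_distance_map(m0)[ref$skeleton]
  d1 <- edge_distance_map(big)[ref$skeleton]
  expect_true(all(d1 - d0 >= 0))
  expect_true(all(d1 - d0 <= 1.5))
})

test_that("claudin intensity normalises by vascular length", {
  stack <- z_stack(list(kdrl = array(100, c(4, 10, 10)),
                        claudin = array(8, c(4, 10, 10))), c(1, 1, 1))
  mask <- array(FALSE, c(4, 10, 10)); mask[2:3, 3:6, 3:6] <- TRUE
  # uniform GFP g over length L -> g / L
  expect_equal(claudin_intensity(stack, "claudin", mask, 40), 0.2)
  # doubling the length halves the normalised value
  expect_equal(claudin_intensity(stack, "claudin", mask, 80), 0.1)
  # zero GFP -> 0
  dark <- stack; dark$voxels$claudin[] <- 0
  expect_equal(claudin_intensity(dark, "claudin", mask, 40), 0)
  expect_error(claudin_intensity(stack, "claudin", mask, 0), "zero-length")
})
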