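# End-to-end experiment orchestration over synthetic cohorts (or loaded data):
# simulate/load -> quantify -> tabulate -> period and group statistics, with
# one root seed and deterministic per-animal seed derivation.

#' Run a full neurovascular-coupling experiment on a simulated cohort
#'
#' For every animal in every group, simulates the erythrocyte and calcium
#' channels (two trials each), quantifies per-period RBC speed and calcium
#' peak rates, collects everything into a result table, and runs the
#' period-wise and group-wise statistics.
#'
#' @param cfg config list (see \code{\link{default_config}}); the blocks used
#'   here are the acquisition constants, \code{rbc}, \code{calcium},
#'   \code{stats}, and \code{cohort}: a list of groups, each
#'   \code{list(name, n, v_base, v_resp, calcium_events, calcium_amplitudes)}.
#' @param n_trials trials per animal (averaged before statistics when
#'   \code{cfg$stats$average_trials}).
#' @param out_dir optional directory; when given, the result table CSV, the
#'   test reports (JSON) and a provenance log (config copy, seed, file
#'   hashes) are written there.
#' @return list with \code{table} (result table), \code{reports} (named
#'   \code{test_report}s), \code{seed}, \code{config}.
#' @export
run_nvc_experiment <- function(cfg = default_config(), n_trials = 2,
                               out_dir = NULL) {
  validate_config(cfg)
  if (is.null(cfg$cohort))
    cfg$cohort <- list(list(name = "control", n = 5, v_base = 300, v_resp = 360,
                            calcium_events = c(0.3, cfg$stimulus_duration + 0.3),
                            calcium_amplitudes = 0.5))
  windows <- define_periods(cfg$stimulus_onset, cfg$stimulus_duration,
                            cfg$baseline_len, cfg$response_len, cfg$recovery_len)
  tree <- .default_flow_tree()
  rows <- list()
  animal_no <- 0L
  for (grp in cfg$cohort) {
    if (is.null(grp$n) || grp$n < 1) stop("empty group: ", grp$name)
    for (a in seq_len(grp$n)) {
      animal_no <- animal_no + 1L
      aid <- sprintf("%s_%02d", grp$name, a)
      per_trial <- list()
      for (tr in seq_len(n_trials)) {
        seed_flow <- derive_seed(cfg$seed, "flow", animal_no * 100L + tr)
        seed_ca <- derive_seed(cfg$seed, "calcium", animal_no * 100L + tr)
        sim <- simulate_rbc_movie(tree, v_base = grp$v_base,
                                  v_resp = grp$v_resp,
                                  windows = windows, fps = cfg$fps,
                                  pixel_size = cfg$pixel_size,
                                  noise_sd = 2, seed = seed_flow)
        st <- quantify_rbc(sim$movie, cfg, windows)
        ca_truth <- calcium_truth(grp$calcium_events %||% numeric(0),
                                  grp$calcium_amplitudes %||% 0.5)
        ca <- simulate_calcium_movie(ca_truth, windows, fps = cfg$fps,
                                     noise_sd = 3, seed = seed_ca)
        ct <- compute_dff(ca$movie, ca$tectum_roi, ca$background_roi,
                          baseline_window = min(cfg$calcium$baseline_window,
                                                cfg$baseline_len))
        ps <- detect_peaks(ct, k_sd = cfg$calcium$k_sd,
                           min_separation = cfg$calcium$min_separation,
                           baseline = windows$baseline,
                           abs_threshold = cfg$calcium$abs_threshold)
        pf_tab <- peak_frequency(ps, windows)
        per_trial[[tr]] <- list(speed = st$period_means, delta = st$delta_um_s,
                                rate = setNames(pf_tab$rate_hz, pf_tab$period))
      }
      agg <- if (cfg$stats$average_trials) {
        list(speed = Reduce(`+`, lapply(per_trial, `[[`, "speed")) / n_trials,
             delta = mean(vapply(per_trial, `[[`, 0, "delta")),
             rate = Reduce(`+`, lapply(per_trial, `[[`, "rate")) / n_trials)
      } else per_trial[[1]]
      trial_tag <- if (cfg$stats$average_trials) "avg" else "1"
      for (p in period_names) {
        rows[[length(rows) + 1L]] <- result_rows(aid, grp$name, trial_tag, p,
                                                 "rbc_speed", agg$speed[[p]], "um/s")
        rows[[length(rows) + 1L]] <- result_rows(aid, grp$name, trial_tag, p,
                                                 "peak_rate", agg$rate[[p]], "peaks/s")
      }
      rows[[length(rows) + 1L]] <- result_rows(aid, grp$name, trial_tag, "response",
                                               "delta_rbc_speed", agg$delta, "um/s")
    }
  }
  tab <- do.call(rbind, rows)
  reports <- .nvc_reports(tab, cfg)
  res <- list(table = tab, reports = reports, seed = cfg$seed, config = cfg)
  if (!is.null(out_dir)) .write_outputs(res, out_dir)
  res
}

# standard planar tree used for simulated cohorts: ten parallel tectal
# capillaries (~119 um long, radius 2.4 um) filling a 128 x 208 px frame at
# 0.609 um/px; one cell per vessel keeps every link unambiguous
.default_flow_tree <- function(pixel_size = 0.609) {
  y <- seq(12, 120, by = 12) * pixel_size
  vessel_tree_spec(data.frame(
    x0 = 6 * pixel_size, y0 = y, x1 = 201 * pixel_size, y1 = y,
    z0 = 0, z1 = 0, radius = 2.4),
    background_intensity = 10, vessel_intensity = 10, noise_sd = 0)
}

#' Quantify RBC kinetics of one movie
#'
#' Segmentation -> linking -> speed -> smoothing -> period means, using the
#' config's \code{rbc} block.
#'
#' @param movie an \code{nvc_movie} (erythrocyte channel first).
#' @param cfg config list.
#' @param windows an \code{nvc_periods} (defaults from the config).
#' @return list with \code{trace} (smoothed, aligned \code{speed_trace}),
#'   \code{delta_um_s}, \code{period_means}.
#' @export
quantify_rbc <- function(movie, cfg = default_config(), windows = NULL) {
  if (is.null(windows))
    windows <- define_periods(cfg$stimulus_onset, cfg$stimulus_duration,
                              cfg$baseline_len, cfg$response_len, cfg$recovery_len)
  cs <- segment_rbcs(movie, threshold = cfg$rbc$threshold,
                     min_area = cfg$rbc$min_area, max_area = cfg$rbc$max_area,
                     median_filter = cfg$rbc$median_filter)
  ts <- link_tracks(cs, max_disp = cfg$rbc$max_disp, max_gap = cfg$rbc$max_gap)
  st <- compute_speed(ts, movie = movie)
  st <- smooth_speed(st, bin_s = cfg$rbc$smooth_bin_s,
                     max_interp_gap_s = cfg$rbc$max_interp_gap_s)
  st <- align_trace(st, movie)
  d <- delta_rbc_speed(st, windows)
  list(trace = st, delta_um_s = d$delta_um_s, period_means = d$period_means)
}

.nvc_reports <- function(tab, cfg) {
  reports <- list()
  for (metric in c("rbc_speed", "peak_rate")) {
    sub <- tab[tab$metric == metric, ]
    wide <- reshape_triples(sub)
    if (nrow(wide) >= 3L)
      reports[[paste0(metric, "_periods")]] <-
        compare_periods(wide, alpha = cfg$stats$alpha,
                        shapiro_alpha = cfg$stats$shapiro_alpha,
                        gg_eps_threshold = cfg$stats$gg_eps_threshold)
    if (length(unique(sub$group)) >= 2L)
      reports[[paste0(metric, "_groups")]] <-
        compare_groups(data.frame(value = sub$value, group = sub$group,
                                  period = sub$period),
                       alpha = cfg$stats$alpha)
  }
  reports
}

#' Pivot result-table rows into per-animal period triples
#' @param sub result-table rows of a single metric.
#' @return data.frame with columns baseline, response, recovery (one row per
#'   animal).
#' @export
reshape_triples <- function(sub) {
  ids <- unique(sub$animal_id)
  cols <- lapply(period_names, function(p)
    vapply(ids, function(id) {
      v <- sub$value[sub$animal_id == id & sub$period == p]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)))
  names(cols) <- period_names
  as.data.frame(cols, row.names = NULL)
}

#' Run a vascular-morphometry experiment on simulated cohorts
#'
#' Per animal: a seeded random vessel tree is rendered as a Z-stack, segmented
#' (Otsu), skeletonised, and measured (branch points, total length, mean
#' radius); groups are compared by unpaired t-tests (two groups) on each
#' metric.
#'
#' @param cfg config list; \code{cfg$cohort_morpho} is a list of groups
#'   \code{list(name, n, n_segments)}.
#' @param out_dir optional output directory.
#' @return list with \code{table}, \code{reports}, \code{truths}, \code{seed},
#'   \code{config}.
#' @export
run_morphometry_experiment <- function(cfg = default_config(), out_dir = NULL) {
  validate_config(cfg)
  if (is.null(cfg$cohort_morpho))
    cfg$cohort_morpho <- list(list(name = "control", n = 4, n_segments = 7))
  rows <- list(); truths <- list()
  animal_no <- 0L
  for (grp in cfg$cohort_morpho) {
    if (is.null(grp$n) || grp$n < 1) stop("empty group: ", grp$name)
    for (a in seq_len(grp$n)) {
      animal_no <- animal_no + 1L
      aid <- sprintf("%s_%02d", grp$name, a)
      seed <- derive_seed(cfg$seed, "morpho", animal_no)
      spec <- random_tree_spec(n_segments = grp$n_segments %||% 7, seed = seed)
      sim <- make_vessel_stack(spec, seed = seed)
      vm <- segment_vessels(sim$stack, min_size = cfg$vessels$min_size)
      g <- skeletonize_mip(vm, cluster_px = cfg$vessels$junction_cluster_px,
                           prune_px = cfg$vessels$prune_px)
      len <- measure_lengths(g, pixel_size = sim$stack$voxel_size[3])
      rad <- measure_radii(g, pixel_size = sim$stack$voxel_size[3])
      truths[[aid]] <- sim$truth
      rows[[length(rows) + 1L]] <- result_rows(
        aid, grp$name, "1", "anatomy",
        c("branch_points", "total_length", "mean_radius"),
        c(nrow(g$branch_points), len$total_um, rad$mean_um),
        c("count", "um", "um"))
    }
  }
  tab <- do.call(rbind, rows)
  reports <- list()
  groups <- unique(tab$group)
  if (length(groups) == 2L)
    for (metric in c("branch_points", "total_length", "mean_radius")) {
      va <- tab$value[tab$metric == metric & tab$group == groups[1]]
      vb <- tab$value[tab$metric == metric & tab$group == groups[2]]
      if (length(va) >= 2L && length(vb) >= 2L && (sd(va) > 0 || sd(vb) > 0))
        reports[[metric]] <- two_group(va, vb)
    }
  res <- list(table = tab, reports = reports, truths = truths,
              seed = cfg$seed, config = cfg)
  if (!is.null(out_dir)) .write_outputs(res, out_dir)
  res
}

#' Seeded random binary vessel tree
#'
#' Grows a planar branching tree of \code{n_segments} tubes inside the default
#' stack volume, breadth-first: each visited tip sprouts two children whose
#' headings diverge by at least ~50 degrees while the whole tree advances in
#' +x, so segments never cross in projection and the topology (hence the
#' branch-point count) is known by construction.
#'
#' @param n_segments number of tubes.
#' @param radius_um tube radius (recycled).
#' @param seed RNG seed.
#' @return a \code{vessel_tree_spec}.
#' @export
random_tree_spec <- function(n_segments = 7, radius_um = 2.5, seed = 1) {
  for (attempt in 0:49) {
    spec <- .grow_tree(n_segments, radius_um, seed + attempt * 100003L)
    if (.tree_is_clean(spec)) return(spec)
  }
  stop("could not grow a non-colliding tree; relax n_segments or radius")
}

# non-adjacent tube axes must stay a diameter apart for the analytic truth
# (branch points, lengths) to survive rasterisation
.tree_is_clean <- function(spec, margin = 4) {
  s <- spec$segments
  lo <- max(s$radius) + 1.5
  if (any(c(s$x0, s$x1, s$y0, s$y1) < lo) ||
      any(c(s$x0, s$x1, s$y0, s$y1) > 127 - lo)) return(FALSE)
  n <- nrow(s)
  if (n < 2L) return(TRUE)
  pts <- lapply(seq_len(n), function(i) {
    tt <- seq(0, 1, length.out = max(2, ceiling(spec$length[i] * 2)))
    cbind(s$x0[i] + tt * (s$x1[i] - s$x0[i]),
          s$y0[i] + tt * (s$y1[i] - s$y0[i]), 0)
  })
  key <- function(x, y) paste(round(x, 4), round(y, 4))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(
      c(key(s$x0[i], s$y0[i]), key(s$x1[i], s$y1[i])),
      c(key(s$x0[j], s$y0[j]), key(s$x1[j], s$y1[j])))) > 0
    a <- c(s$x0[j], s$y0[j], 0); b <- c(s$x1[j], s$y1[j], 0)
    d <- sqrt(.dist2_to_segment(pts[[i]], a, b))
    lim <- s$radius[i] + s$radius[j] + margin
    if (shared) {
      # adjacent tubes meet at the node; require clearance away from it only
      far <- d > 1e-9 & sqrt(rowSums(sweep(pts[[i]], 2, a)^2)) >
        2 * lim & sqrt(rowSums(sweep(pts[[i]], 2, b)^2)) > 2 * lim
      if (any(d[far] < lim)) return(FALSE)
    } else if (any(d < lim)) return(FALSE)
  }
  TRUE
}

.grow_tree <- function(n_segments, radius_um, seed) {
  set.seed(seed %% 2147483647L)
  h1 <- runif(1, -0.1, 0.1)
  len1 <- runif(1, 36, 42)
  segs <- data.frame(x0 = 12, y0 = 64, z0 = 30,
                     x1 = 12 + len1 * cos(h1), y1 = 64 + len1 * sin(h1),
                     z1 = 30)
  tips <- list(list(x = segs$x1, y = segs$y1, h = h1, depth = 1L))
  # segment lengths shrink with depth so the tree stays inside the volume
  len_rng <- list(c(36, 42), c(26, 34), c(20, 26), c(16, 20))
  while (nrow(segs) < n_segments && length(tips)) {
    tip <- tips[[1]]; tips <- tips[-1]
    for (sgn in c(-1, 1)) {
      if (nrow(segs) >= n_segments) break
      ang <- tip$h + sgn * runif(1, 0.55, 0.75)
      rng <- len_rng[[min(tip$depth + 1L, length(len_rng))]]
      len <- runif(1, rng[1], rng[2])
      x1 <- tip$x + len * cos(ang)
      y1 <- tip$y + len * sin(ang)
      segs <- rbind(segs, data.frame(x0 = tip$x, y0 = tip$y, z0 = 30,
                                     x1 = x1, y1 = y1, z1 = 30))
      tips <- c(tips, list(list(x = x1, y = y1, h = ang,
                                depth = tip$depth + 1L)))
    }
  }
  segs$radius <- rep_len(radius_um, nrow(segs))
  vessel_tree_spec(segs, background_intensity = 10, vessel_intensity = 200,
                   noise_sd = 4)
}

.write_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab_path <- file.path(out_dir, "results.csv")
  write_result_table(res$table, tab_path)
  rep_list <- lapply(res$reports, function(r) r[c("test", "statistic", "p",
                                                 "gate_parametric")])
  jsonlite::write_json(rep_list, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- list(seed = res$seed,
               results_sha = unname(tools::md5sum(tab_path)),
               config = res$config)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
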