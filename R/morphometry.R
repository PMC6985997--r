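# Vascular morphometry: Otsu segmentation of the endothelial channel,
# 2-D maximum-intensity-projection centrelines by thinning, branch points,
# segment lengths, and radii as the exact Euclidean distance from centreline
# pixels to the segmented vessel edge.

#' Segment vasculature from a Z-stack by global Otsu thresholding
#'
#' A single Otsu threshold is computed over the whole channel (256-bin
#' histogram) to accommodate variable vessel fluorescence, followed by removal
#' of connected components smaller than \code{min_size} voxels
#' (6-connectivity); the largest component is always retained.
#'
#' @param stack an \code{nvc_zstack}.
#' @param channel channel name (default first).
#' @param min_size minimum component size in voxels.
#' @param bright_vessels TRUE if vessels are brighter than background;
#'   FALSE inverts the comparison.
#' @return a \code{vessel_mask}: list with \code{mask} (logical
#'   \code{[z, y, x]}), \code{threshold} (intensity units), \code{min_size}.
#' @export
segment_vessels <- function(stack, channel = names(stack$voxels)[1],
                            min_size = 50, bright_vessels = TRUE) {
  if (!channel %in% names(stack$voxels)) stop("no channel named ", channel)
  arr <- stack$voxels[[channel]]
  rng <- range(arr)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold undefined")
  norm <- (as.vector(arr) - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)),
                         range = c(0, 1), levels = 256L)
  thr <- rng[1] + thr01 * diff(rng)
  mask <- if (bright_vessels) arr > thr else arr < thr
  if (!any(mask)) stop("segmentation produced an empty mask")
  mask <- .filter_components_3d(mask, min_size)
  structure(list(mask = mask, threshold = thr, min_size = min_size),
            class = "vessel_mask")
}

# 6-connected 3-D component filtering via an igraph over foreground voxels
.filter_components_3d <- function(mask, min_size) {
  idx <- which(mask)
  if (!length(idx)) return(mask)
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  id <- array(0L, d); id[idx] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    q <- pos; q[, ax] <- q[, ax] + 1L
    ok <- q[, ax] <= d[ax]
    nb <- rep(0L, nrow(pos))
    nb[ok] <- id[q[ok, , drop = FALSE]]
    has <- nb > 0L
    if (any(has)) edges <- rbind(edges, cbind(which(has), nb[has]))
  }
  comp <- if (is.null(edges)) {
    list(membership = seq_along(idx), csize = rep(1L, length(idx)))
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    igraph::components(g)
  }
  keep_comp <- which(comp$csize >= min_size | comp$csize == max(comp$csize))
  keep <- comp$membership %in% keep_comp
  out <- array(FALSE, d)
  out[idx[keep]] <- TRUE
  out
}

#' Project a 3-D vessel mask onto the imaging plane
#' @param vm a \code{vessel_mask} or logical array \code{[z, y, x]}.
#' @return logical matrix \code{(y, x)}.
#' @export
project_mask <- function(vm) {
  m <- if (inherits(vm, "vessel_mask")) vm$mask else vm
  if (length(dim(m)) == 2L) return(m != 0)
  apply(m, c(2, 3), any)
}

#' Extract the centreline graph from a vessel mask
#'
#' The binary mask is max-projected along z, thinned to a 1-px 8-connected
#' skeleton, and short spurs are pruned. Junction pixels (>= 3 skeleton
#' neighbours) lying within \code{cluster_px} of each other are merged into
#' single branch points; segments are the skeleton paths between
#' junctions/endpoints.
#'
#' @param vm a \code{vessel_mask} (3-D or 2-D) or logical matrix.
#' @param cluster_px minimum junction clustering radius in pixels; junction
#'   pixels also merge whenever they lie within the sum of their local vessel
#'   radii (one junction complex per anatomical branch point).
#' @param prune_px spur-pruning threshold in pixels.
#' @return a \code{vessel_graph}: list with \code{skeleton} (logical matrix),
#'   \code{mask2d}, \code{branch_points} (data.frame \code{y, x}, 0-based
#'   cluster centroids), \code{endpoints}, and \code{segments} (list of
#'   ordered 0-based \code{(y, x)} path matrices with a \code{steps_px}
#'   attribute).
#' @export
skeletonize_mip <- function(vm, cluster_px = 2, prune_px = 5) {
  mask2d <- project_mask(vm)
  if (!any(mask2d)) stop("empty vessel mask")
  sk <- thin_mask(mask2d)
  sk <- prune_spurs(sk, prune_px)
  pg <- .pixel_graph(sk)
  deg <- igraph::degree(pg$graph)
  jpix <- pg$pos[deg >= 3L, , drop = FALSE]
  epix <- pg$pos[deg == 1L, , drop = FALSE]

  # cluster junction pixels: single linkage, merging pixels closer than the
  # sum of their local radii (never less than cluster_px)
  jmem <- integer(0)
  branch_points <- data.frame(y = numeric(0), x = numeric(0))
  if (nrow(jpix)) {
    dmap <- edge_distance_map(mask2d)
    rloc <- dmap[jpix] + 0.5
    dmat <- as.matrix(dist(jpix))
    thr <- outer(rloc, rloc, "+")
    adj <- dmat <= pmax(thr, cluster_px)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    jmem <- igraph::components(g)$membership
    bp <- do.call(rbind, lapply(split(seq_len(nrow(jpix)), jmem), function(ii)
      colMeans(jpix[ii, , drop = FALSE]) - 1))
    branch_points <- data.frame(y = bp[, 1], x = bp[, 2], row.names = NULL)
  }

  segments <- .trace_segments(pg, deg, jmem)
  # absorb short bridges that connect junction pixels of one cluster: they are
  # part of the junction complex, not vessel segments
  if (length(segments)) {
    is_bridge <- vapply(segments, function(s) {
      cl <- attr(s, "end_clusters")
      length(cl[[1]]) > 0 && length(cl[[2]]) > 0 &&
        length(intersect(cl[[1]], cl[[2]])) > 0 &&
        attr(s, "steps_px") <= 2 * max(cluster_px, prune_px)
    }, logical(1))
    bridge_px <- sum(vapply(segments[is_bridge], function(s)
      attr(s, "steps_px"), numeric(1)))
    segments <- segments[!is_bridge]
    attr(segments, "bridge_px") <- bridge_px
  }
  structure(list(skeleton = sk, mask2d = mask2d,
                 branch_points = branch_points,
                 endpoints = if (nrow(epix))
                   data.frame(y = epix[, 1] - 1, x = epix[, 2] - 1)
                 else data.frame(y = numeric(0), x = numeric(0)),
                 segments = segments),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d skeleton px, %d branch point(s), %d segment(s), %d endpoint(s)\n",
              sum(x$skeleton), nrow(x$branch_points), length(x$segments),
              nrow(x$endpoints)))
  invisible(x)
}

# reduced pixel graph of a skeleton: all 4-adjacent pairs are edges
# (weight 1); diagonal pairs are edges (weight sqrt(2)) only when they share
# no common 4-neighbour in the skeleton, so staircase doubles and junction
# surrounds do not create shortcut degrees
.pixel_graph <- function(sk) {
  idx <- which(sk)
  d <- dim(sk)
  pos <- which(sk, arr.ind = TRUE)
  id <- matrix(0L, d[1], d[2]); id[idx] <- seq_along(idx)
  nbr_id <- function(dy, dx) {
    q <- cbind(pos[, 1] + dy, pos[, 2] + dx)
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2]
    nb <- rep(0L, nrow(pos))
    nb[ok] <- id[q[ok, , drop = FALSE]]
    nb
  }
  nN <- nbr_id(-1, 0); nS <- nbr_id(1, 0); nW <- nbr_id(0, -1); nE <- nbr_id(0, 1)
  edges <- NULL; wts <- NULL
  for (e in list(list(nS, 1), list(nE, 1))) {
    has <- e[[1]] > 0L
    if (any(has)) {
      edges <- rbind(edges, cbind(which(has), e[[1]][has]))
      wts <- c(wts, rep(e[[2]], sum(has)))
    }
  }
  # diagonals, dropped when a 4-path exists through a shared neighbour
  # (for the SE diagonal the shared 4-neighbours are exactly S and E, etc.)
  for (ds in list(list(1, 1, nS, nE), list(1, -1, nS, nW))) {
    nb <- nbr_id(ds[[1]], ds[[2]])
    keep <- nb > 0L & ds[[3]] == 0L & ds[[4]] == 0L
    if (any(keep)) {
      edges <- rbind(edges, cbind(which(keep), nb[keep]))
      wts <- c(wts, rep(sqrt(2), sum(keep)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)), weight = wts)
  list(graph = g, pos = pos, id = id)
}

# split the skeleton at junction pixels (reduced-graph degree >= 3) and trace
# each remaining path; each segment records its ordered pixels, its step
# length in px (including the connecting step to an adjacent junction pixel at
# either end), and the junction clusters its two ends touch
.trace_segments <- function(pg, deg, jmem = integer(0)) {
  keep <- which(deg < 3L)
  if (!length(keep)) return(list())
  jvert <- which(deg >= 3L)
  sub_all <- igraph::induced_subgraph(pg$graph, keep)
  comp <- igraph::components(sub_all)
  segs <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(sub_all, vids)
    dsub <- igraph::degree(sub)
    if (any(dsub <= 1L)) {
      ends <- which(dsub <= 1L)
      a <- ends[1]; b <- if (length(ends) > 1L) ends[length(ends)] else ends[1]
      sp <- igraph::shortest_paths(sub, from = a, to = b,
                                   weights = igraph::E(sub)$weight)$vpath[[1]]
      ord <- keep[vids[as.integer(sp)]]
    } else ord <- keep[vids]                # cycle: arbitrary order
    px <- pg$pos[ord, , drop = FALSE]
    steps <- if (nrow(px) > 1L)
      sum(sqrt(rowSums((px[-1L, , drop = FALSE] -
                        px[-nrow(px), , drop = FALSE])^2)))
    else 0
    # an end adjacent to a junction complex connects to that complex's
    # centroid (the reported branch point), so the complex's span is counted
    jpos <- pg$pos[jvert, , drop = FALSE]
    end_clusters <- list(integer(0), integer(0))
    connect <- 0
    ei <- 0L
    for (endpix in list(px[1L, ], px[nrow(px), ])) {
      ei <- ei + 1L
      if (!nrow(jpos)) next
      dy <- abs(jpos[, 1] - endpix[1]); dx <- abs(jpos[, 2] - endpix[2])
      adj <- which(dy <= 1 & dx <= 1 & (dy + dx) > 0)
      if (length(adj)) {
        if (length(jmem)) {
          end_clusters[[ei]] <- unique(jmem[adj])
          cl <- jmem[adj[which.min(dy[adj]^2 + dx[adj]^2)]]
          cen <- colMeans(jpos[jmem == cl, , drop = FALSE])
          connect <- connect +
            sqrt((cen[1] - endpix[1])^2 + (cen[2] - endpix[2])^2)
        } else {
          connect <- connect + min(sqrt(dy[adj]^2 + dx[adj]^2))
        }
      }
    }
    seg <- px - 1                           # 0-based
    colnames(seg) <- c("y", "x")
    attr(seg, "steps_px") <- steps + connect
    attr(seg, "connect_px") <- connect
    attr(seg, "end_clusters") <- end_clusters
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

#' Vessel lengths from a centreline graph
#'
#' Per segment, the centreline path length in pixels times the pixel size.
#' With \code{stride = 1} the path length is the raw sum of centreline steps
#' (1 for a 4-neighbour step, sqrt(2) for a diagonal); that metric inflates
#' oblique vessels by up to ~14% through staircase zigzag, so by default the
#' path is resampled every \code{stride} pixels and chord lengths are summed,
#' which is unbiased for straight tubes at any orientation. Thinning also
#' retracts a tube's centreline from its rounded end by roughly one radius;
#' with \code{extend_tips} each free segment end is prolonged along its local
#' direction to the mask boundary minus the local radius (the rounded cap),
#' removing that bias.
#'
#' At a bifurcation the child tubes merge into one throat for roughly one
#' local radius before their centrelines separate, so the skeleton traverses
#' that stretch once while the vessel axes cover it twice;
#' \code{junction_correction} adds one local radius per branch point to
#' compensate.
#'
#' @param g a \code{vessel_graph}.
#' @param pixel_size micrometres per pixel.
#' @param extend_tips extend free ends to the vessel-mask boundary.
#' @param stride chord resampling interval in pixels (1 = raw step metric).
#' @param junction_correction add the local radius at each branch point.
#' @return list with \code{total_um} and \code{per_segment_um} (the junction
#'   correction appears only in the total).
#' @export
measure_lengths <- function(g, pixel_size = 0.609, extend_tips = TRUE,
                            stride = 5, junction_correction = TRUE) {
  if (!length(g$segments)) stop("vessel graph has no segments")
  ep_key <- paste(g$endpoints$y, g$endpoints$x)
  dmap <- if (extend_tips || (junction_correction && nrow(g$branch_points)))
    edge_distance_map(g$mask2d)
  per <- vapply(g$segments, function(s) {
    steps <- .chord_length(s, stride) + attr(s, "connect_px")
    if (extend_tips && nrow(s) >= 2L) {
      for (end in c(1L, nrow(s))) {
        if (!paste(s[end, 1], s[end, 2]) %in% ep_key) next
        back <- min(3L, nrow(s) - 1L)
        ref <- if (end == 1L) s[1L + back, ] else s[nrow(s) - back, ]
        dir <- s[end, ] - ref
        nrm <- sqrt(sum(dir^2))
        if (nrm == 0) next
        dir <- dir / nrm
        ext <- 0
        for (k in seq_len(30L)) {
          q <- round(s[end, ] + k * dir) + 1L   # back to 1-based indices
          if (q[1] < 1 || q[2] < 1 || q[1] > nrow(g$mask2d) ||
              q[2] > ncol(g$mask2d) || !g$mask2d[q[1], q[2]]) break
          ext <- k
        }
        r_tip <- dmap[s[end, 1] + 1L, s[end, 2] + 1L] + 0.5
        steps <- steps + max(0, ext - r_tip)
      }
    }
    steps
  }, numeric(1)) * pixel_size
  total <- sum(per)
  if (junction_correction && nrow(g$branch_points))
    total <- total + sum(dmap[cbind(round(g$branch_points$y) + 1L,
                                    round(g$branch_points$x) + 1L)] + 0.5) *
      pixel_size
  list(total_um = total, per_segment_um = per)
}

# polyline length of an ordered 0-based pixel path, resampled every `stride`
.chord_length <- function(s, stride) {
  n <- nrow(s)
  if (n < 2L) return(0)
  idx <- unique(c(seq(1L, n, by = max(1L, stride)), n))
  p <- s[idx, , drop = FALSE]
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Exact distance maps over a binary mask
#'
#' \code{edge_distance_map} gives, for every pixel, the exact Euclidean
#' distance to the nearest vessel-edge pixel (foreground pixels 4-adjacent to
#' background or to the image border). \code{background_distance_map} gives
#' the distance of foreground pixels to the nearest background pixel.
#'
#' @param mask logical matrix \code{(y, x)}.
#' @return numeric matrix of distances in pixels.
#' @export
edge_distance_map <- function(mask) {
  m <- mask != 0
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  interior <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] &
    pad[1:nrow(m), 2:(ncol(m) + 1)] & pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] &
    pad[2:(nrow(m) + 1), 1:ncol(m)] & pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
  edge <- m & !interior
  if (!any(edge)) stop("mask has no edge pixels")
  # EBImage::distmap measures non-zero pixels to the nearest zero pixel
  dm <- EBImage::distmap(EBImage::Image(t(1 - edge)), metric = "euclidean")
  t(EBImage::imageData(dm))
}

#' @rdname edge_distance_map
#' @export
background_distance_map <- function(mask) {
  m <- mask != 0
  dm <- EBImage::distmap(EBImage::Image(t(m * 1)), metric = "euclidean")
  t(EBImage::imageData(dm))
}

#' Vessel radii along the centreline
#'
#' The radius at each centreline pixel is the exact Euclidean distance to the
#' nearest vessel-edge pixel of the projected mask, plus half a pixel (the
#' edge-pixel centre sits half a pixel inside the physical vessel boundary),
#' converted to micrometres. The histogram counts centreline pixels per
#' half-pixel radius bin.
#'
#' @param g a \code{vessel_graph}.
#' @param mask2d optional projected mask (default: the graph's own).
#' @param pixel_size micrometres per pixel.
#' @return list with \code{radii_um} (per centreline pixel),
#'   \code{radii_px}, \code{mean_um}, and \code{histogram} (data.frame
#'   \code{radius_px}, \code{radius_um}, \code{count}; counts sum to the
#'   number of centreline pixels).
#' @export
measure_radii <- function(g, mask2d = g$mask2d, pixel_size = 0.609) {
  sk_idx <- which(g$skeleton)
  if (any(!mask2d[sk_idx]))
    stop("internal inconsistency: skeleton pixel outside the vessel mask")
  dmap <- edge_distance_map(mask2d)
  r_px <- dmap[sk_idx] + 0.5
  bins <- round(r_px * 2) / 2
  tab <- table(bins)
  hist <- data.frame(radius_px = as.numeric(names(tab)),
                     count = as.integer(tab))
  hist$radius_um <- hist$radius_px * pixel_size
  list(radii_um = r_px * pixel_size, radii_px = r_px,
       mean_um = mean(r_px) * pixel_size,
       histogram = hist[, c("radius_px", "radius_um", "count")])
}

#' Vascular-density-normalised claudin-5a reporter intensity
#'
#' Mean junctional-GFP intensity over the vessel mask voxels, divided by the
#' total vascular centreline length (the density proxy), removing bias from
#' treatment-induced differences in vascular length.
#'
#' @param stack an \code{nvc_zstack} containing the GFP channel.
#' @param gfp_channel channel name.
#' @param vessel_mask a \code{vessel_mask} from the endothelial channel of the
#'   same stack.
#' @param total_length_um total vessel length from \code{measure_lengths}.
#' @return normalised intensity in a.u. per micrometre.
#' @export
claudin_intensity <- function(stack, gfp_channel, vessel_mask, total_length_um) {
  if (!gfp_channel %in% names(stack$voxels)) stop("no channel named ", gfp_channel)
  if (total_length_um <= 0) stop("zero-length vasculature")
  m <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else vessel_mask
  if (!any(m)) stop("empty vessel mask")
  mean(stack$voxels[[gfp_channel]][m]) / total_length_um
}
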