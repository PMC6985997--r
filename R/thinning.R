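# Morphological thinning (Zhang & Suen 1984) to a 1-px-wide 8-connected
# skeleton, plus spur pruning. Vectorised over the whole frame per iteration.

.shift2 <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# 8-neighbourhood stack in the clockwise order P2..P9 = N, NE, E, SE, S, SW, W, NW
.neighbours8 <- function(m) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(offs, function(o) .shift2(m, o[1], o[2]))
}

#' Thin a binary image to its 1-px skeleton
#'
#' Iterative two-subfield thinning; the result is an 8-connected centreline
#' preserving the topology of the input mask.
#'
#' @param mask logical or 0/1 matrix \code{(y, x)}.
#' @return logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- .neighbours8(m)
      B <- Reduce(`+`, nb)
      ring <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i)
        (ring[[i]] == 0L) * (ring[[i + 1L]] == 1L)))
      if (step == 1L) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L   # P2*P4*P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L   # P4*P6*P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L   # P2*P4*P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L   # P2*P6*P8
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# number of 8-neighbours of each skeleton pixel
.neighbour_count <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  Reduce(`+`, .neighbours8(m)) * sk
}

# ring crossing number: 0->1 transitions around the 8-neighbour ring.
# 1 = endpoint, 2 = path pixel (even across staircase doubles), >= 3 = junction
.ring_transitions <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  nb <- .neighbours8(m)
  ring <- c(nb, nb[1])
  A <- Reduce(`+`, lapply(1:8, function(i)
    (ring[[i]] == 0L) * (ring[[i + 1L]] == 1L)))
  A * sk
}

#' Prune short skeleton spurs
#'
#' Removes terminal branches shorter than \code{min_px} pixels that end at a
#' junction (thinning artefacts at tube ends and junctions). Branch structure
#' is taken from the reduced pixel graph, so staircase doubles on a path are
#' not mistaken for junctions, and pruning never removes an isolated path.
#'
#' @param sk logical skeleton matrix.
#' @param min_px spur length threshold in pixels.
#' @return pruned logical matrix.
#' @export
prune_spurs <- function(sk, min_px = 5) {
  if (min_px <= 0) return(sk)
  repeat {
    pg <- .pixel_graph(sk)
    deg <- igraph::degree(pg$graph)
    ends <- which(deg == 1L)
    removed_any <- FALSE
    for (e in ends) {
      path <- e
      cur <- e; prev <- 0L
      hit_junction <- FALSE
      for (step in seq_len(min_px)) {
        nbs <- setdiff(as.integer(igraph::neighbors(pg$graph, cur)), prev)
        if (!length(nbs)) break
        if (deg[nbs[1]] >= 3L) { hit_junction <- TRUE; break }
        prev <- cur; cur <- nbs[1]
        path <- c(path, cur)
      }
      if (hit_junction && length(path) < min_px) {
        sk[pg$pos[path, , drop = FALSE]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  sk
}

# number of 8-neighbours of each skeleton pixel
.neighbour_count <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  Reduce(`+`, .neighbours8(m)) * sk
}

# ring crossing number: 0->1 transitions around the 8-neighbour ring.
# 1 = endpoint, 2 = path pixel (even across staircase doubles), >= 3 = junction
.ring_transitions <- function(sk) {
  m <- matrix(as.integer(sk), nrow(sk), ncol(sk))
  nb <- .neighbours8(m)
  ring <- c(nb, nb[1])
  A <- Reduce(`+`, lapply(1:8, function(i)
    (ring[[i]] == 0L) * (ring[[i + 1L]] == 1L)))
  A * sk
}

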