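# 2D skeletonization and skeleton graph utilities. Thinning follows the
# Zhang-Suen algorithm; geodesic lengths weight orthogonal steps 1 px and
# diagonal steps sqrt(2) px.

# Shift a logical matrix by (dy, dx) with FALSE fill.
shiftl <- function(m, dy, dx) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)) - dy; xs <- seq_len(ncol(m)) - dx
  oky <- ys >= 1 & ys <= nrow(m); okx <- xs >= 1 & xs <= ncol(m)
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels border pixels that do not break 8-connectivity until
#' a one-pixel-wide skeleton remains.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  img <- mask > 0
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in the conventional order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      p2 <- shiftl(img, 1, 0);  p3 <- shiftl(img, 1, -1)
      p4 <- shiftl(img, 0, -1); p5 <- shiftl(img, -1, -1)
      p6 <- shiftl(img, -1, 0); p7 <- shiftl(img, -1, 1)
      p8 <- shiftl(img, 0, 1);  p9 <- shiftl(img, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- img & B >= 2 & B <= 6 & A == 1
      if (step == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Number of 8-neighbours of every skeleton pixel.
skel_neighbor_count <- function(skel) {
  n <- matrix(0, nrow(skel), ncol(skel))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    n <- n + shiftl(skel, dy, dx)
  }
  n
}

#' Skeleton endpoints
#'
#' Skeleton pixels with at most one skeleton neighbour — process tips (and
#' branch stumps).
#'
#' @param skel logical skeleton matrix.
#' @return matrix of `(y, x)` endpoint coordinates.
#' @export
skeleton_endpoints <- function(skel) {
  nb <- skel_neighbor_count(skel)
  which(skel & nb <= 1, arr.ind = TRUE)
}

# Geodesic distances (px, diagonal = sqrt(2)) from a source pixel to every
# pixel of a skeleton component, with predecessors so paths can be
# reconstructed. pts: (n x 2) coords; src: row index. Dijkstra on the
# pixel set; components are small (tens of pixels).
geodesic_dist <- function(pts, src) {
  n <- nrow(pts)
  dist <- rep(Inf, n); dist[src] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    dy <- abs(pts[, 1] - pts[u, 1]); dx <- abs(pts[, 2] - pts[u, 2])
    nb <- which(!done & dy <= 1 & dx <= 1)
    if (length(nb)) {
      w <- ifelse(dy[nb] + dx[nb] == 2, sqrt(2), 1)
      upd <- dist[u] + w < dist[nb]
      dist[nb[upd]] <- dist[u] + w[upd]
      prev[nb[upd]] <- u
    }
  }
  list(dist = dist, prev = prev)
}

# Length (px) of the geodesic path src -> dst through a skeleton component,
# measured on the path polyline resampled every `stride` pixels. The raw
# sqrt(2)-weighted chain length overestimates digital straight lines by up
# to ~8% at shallow angles; resampling removes the staircase bias.
path_length_px <- function(pts, gd, dst, stride = 5) {
  path <- dst
  while (!is.na(gd$prev[path[1]])) path <- c(gd$prev[path[1]], path)
  p <- pts[path, , drop = FALSE]
  n <- nrow(p)
  if (n < 2) return(0)
  idx <- unique(c(seq(1, n, by = stride), n))
  seg <- diff(p[idx, 1])^2 + diff(p[idx, 2])^2
  sum(sqrt(seg))
}
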