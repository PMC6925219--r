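# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a `vq_*` condition class so
#' callers (and tests) can distinguish failure modes programmatically.
#' @noRd
vq_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vq_error")))
}

#' Shift a matrix by an integer offset
#'
#' `out[y, x] = m[y - dy, x - dx]`; pixels that fall outside the source are
#' set to `fill`. This is the forward model used both when rendering frame
#' jitter and when undoing it after registration.
#' @noRd
shift_int <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy   # source rows
  xs <- seq_len(nc) - dx
  oky <- ys >= 1L & ys <= nr
  okx <- xs >= 1L & xs <= nc
  if (any(oky) && any(okx)) {
    out[oky, okx] <- m[ys[oky], xs[okx]]
  }
  out
}

#' Most frequent intensity value of an image
#'
#' Used as the background fill for registration borders: on fluorescence
#' images the modal value is the background plateau, so filling with it does
#' not bias extravascular means. Values are rounded to 6 decimals before
#' tabulation so that float noise does not fragment the mode.
#' @noRd
image_mode <- function(x) {
  v <- round(as.vector(x), 6)
  tab <- table(v)
  as.numeric(names(tab)[which.max(tab)])
}

# Logical matrix from an EBImage result (Image objects are arrays).
ebi_bin <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m > 0.5
}

#' 8-connected labeling of a binary mask
#'
#' EBImage's bwlabel() is 4-connected; particle analysis here follows the
#' ImageJ convention of 8-connectivity. Diagonally adjacent 4-connected
#' labels are merged with a union-find over the (small) label set.
#' @noRd
label8 <- function(mask) {
  mode(mask) <- "numeric"
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  dim(lab) <- dim(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # label pairs that touch along either diagonal
  p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
  p2 <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find_root(pairs[k, 1]); b <- find_root(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find_root, integer(1) + 0)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Per-component pixel counts and centroids
#' @noRd
component_table <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) {
    return(data.frame(label = integer(0), n_px = integer(0),
                      centroid_y = numeric(0), centroid_x = numeric(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  data.frame(
    label = ids,
    n_px = as.integer(tabulate(l, max(ids))[ids]),
    centroid_y = tapply(idx[, 1], l, mean)[as.character(ids)],
    centroid_x = tapply(idx[, 2], l, mean)[as.character(ids)],
    row.names = NULL
  )
}

#' 32-bit FNV-1a hash of a character string
#'
#' Deterministic, dependency-free hash used for config fingerprints in report
#' rows and for deriving named RNG substreams from the root seed.
#' @noRd
fnv32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    # h * 16777619 mod 2^32, split to stay within double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# XOR for doubles holding 32-bit unsigned values (bitwXor needs < 2^31).
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 2147483648
  x <- bitwXor(as.integer(a %% 2147483648), as.integer(b %% 2147483648))
  if (x < 0) x <- x + 4294967296
  (hi_a + b %/% 2147483648) %% 2 * 2147483648 + x %% 2147483648
}

#' Derive a substream seed from a root seed and a stream name
#'
#' All randomness flows from one root seed; each consumer (scene rendering,
#' noise, jitter) draws from a named substream so adding one consumer never
#' perturbs another. Result is kept below 2^31.
#' @noRd
substream_seed <- function(seed, name) {
  as.integer(fnv32(paste0(seed, ":", name)) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards so generation is reproducible
#' without clobbering the session.
#' @noRd
with_local_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

#' Euclidean distance between two (y, x) points
#' @noRd
pt_dist <- function(a, b) sqrt(sum((a - b)^2))
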