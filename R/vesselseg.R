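#' Maximum-entropy (Kapur) threshold
#'
#' Picks the intensity cut that maximizes the sum of Shannon entropies of
#' the below- and above-threshold partitions of the image histogram, the
#' criterion behind ImageJ's Maximum Entropy thresholder. The histogram
#' uses `n_bins` equal-width bins spanning `[min, max]` of the data (the
#' 8-bit ImageJ convention at the default 256); among tied maxima the
#' smallest threshold is returned, so the result is deterministic.
#'
#' @param image numeric matrix or vector of intensities (>= 2 distinct
#'   values).
#' @param n_bins histogram bins.
#' @return threshold intensity `T`; foreground is `intensity > T`. `T` is
#'   the lower edge of the first foreground bin, so bin membership and the
#'   comparison agree except for values exactly on the edge.
#' @export
max_entropy_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (length(x) < 2) vq_stop("need at least 2 pixels", "vq_bad_image")
  lo <- min(x); hi <- max(x)
  if (lo == hi) vq_stop("constant image has no threshold", "vq_constant_image")
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((x - lo) / w), n_bins - 1)       # 0-based bin index
  p <- tabulate(bin + 1L, n_bins) / length(x)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)          # mass of bins 0..t
  S <- cumsum(plogp)      # sum p log p over bins 0..t
  Stot <- S[n_bins]
  crit <- rep(-Inf, n_bins - 1)
  for (t in seq_len(n_bins - 1)) {                   # split after bin t-1
    Pb <- P[t]
    if (Pb <= 0 || Pb >= 1) next
    Hb <- log(Pb) - S[t] / Pb
    Ha <- log(1 - Pb) - (Stot - S[t]) / (1 - Pb)
    crit[t] <- Hb + Ha
  }
  if (!any(is.finite(crit))) {
    vq_stop("histogram mass falls in one bin; no valid split",
            "vq_constant_image")
  }
  t_star <- which.max(crit)                          # smallest argmax
  lo + t_star * w
}

#' Delineate vessels on a projected dextran image
#'
#' Binarizes at the maximum-entropy threshold, fills interior holes (dark
#' lumen centers), and discards connected components smaller than
#' `min_particle_area_um2` — the "Analyze Particles, size = 40-Infinity,
#' include holes" recipe. Components are 8-connected; the area bound is
#' inclusive; area is pixel count times the squared pixel size.
#'
#' @param image 2D numeric matrix (typically the projected impermeant
#'   dextran channel).
#' @param pixel_size_um lateral calibration.
#' @param config an [analysis_config()].
#' @return object of class `vessel_mask`: list with `mask` (logical
#'   matrix), `labels` (integer matrix), `components` (data frame: label,
#'   area_um2, centroid_y, centroid_x), `threshold` and `pixel_size_um`.
#' @export
vessel_mask <- function(image, pixel_size_um, config = analysis_config()) {
  stopifnot(is.matrix(image), pixel_size_um > 0)
  thr <- max_entropy_threshold(image, config$n_bins)
  bw <- image > thr
  filled <- ebi_bin(EBImage::fillHull(bw * 1))
  lab <- label8(filled)
  comp <- component_table(lab)
  comp$area_um2 <- comp$n_px * pixel_size_um^2
  keep <- comp$label[comp$area_um2 >= config$min_particle_area_um2]
  mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  lab[!mask] <- 0L
  comp <- comp[comp$label %in% keep, , drop = FALSE]
  if (nrow(comp) > 0) {
    lab[lab > 0] <- match(lab[lab > 0], keep)
    comp$label <- seq_len(nrow(comp))
  }
  structure(list(mask = mask, labels = lab,
                 components = comp[, c("label", "area_um2",
                                       "centroid_y", "centroid_x")],
                 threshold = thr, pixel_size_um = pixel_size_um),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d component(s), threshold %.4g, total area %.1f um^2\n",
              nrow(x$mask), ncol(x$mask), nrow(x$components), x$threshold,
              sum(x$components$area_um2)))
  invisible(x)
}

# Mask dilated by k px (8-neighbourhood box), used when excluding a border
# margin around vessels.
dilate_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  ebi_bin(EBImage::dilate(mask * 1, EBImage::makeBrush(2 * k + 1, "box")))
}
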