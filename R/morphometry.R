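#' Count and measure microglial processes
#'
#' Skeletonizes the cell mask outside the soma; each 8-connected skeleton
#' component whose nearest approach to the soma is within `attach_px`
#' counts as one process rooted there. A process's length is the geodesic
#' skeleton distance from its soma-exit pixel to its farthest tip, plus
#' the small gap thinning leaves between the skeleton end and the soma
#' surface, converted to um.
#'
#' @param cell_mask logical matrix covering the whole cell.
#' @param soma_mask logical matrix of the soma (subset of `cell_mask`).
#' @param pixel_size_um lateral calibration.
#' @param attach_um maximum distance (um) from the soma at which a skeleton
#'   component still counts as attached; generous, because thinning
#'   retracts the skeleton from the wide process-soma junction.
#' @param min_length_um shortest accepted process; shorter fragments are
#'   slivers of imperfect soma subtraction, not processes.
#' @return list with `process_count`, `lengths_um` (one per process),
#'   `total_length_um`, `mean_length_um`.
#' @export
trace_processes <- function(cell_mask, soma_mask, pixel_size_um,
                            attach_um = 2.5, min_length_um = 1.5) {
  if (!any(cell_mask)) vq_stop("empty cell mask", "vq_empty_mask")
  if (any(soma_mask & !cell_mask)) {
    vq_stop("soma mask must lie within the cell mask", "vq_bad_mask")
  }
  proc <- cell_mask & !soma_mask
  empty <- list(process_count = 0L, lengths_um = numeric(0),
                total_length_um = 0, mean_length_um = NA_real_)
  if (!any(proc)) return(empty)
  skel <- skeletonize(proc)
  if (!any(skel)) return(empty)
  # distance of every pixel to the soma (0 inside it)
  soma_dist <- EBImage::imageData(EBImage::distmap(1 - soma_mask * 1))
  dim(soma_dist) <- dim(soma_mask)
  lab <- label8(skel)
  lengths <- numeric(0)
  for (l in seq_len(max(lab))) {
    pts <- which(lab == l, arr.ind = TRUE)
    dsoma <- soma_dist[pts]
    if (min(dsoma) * pixel_size_um > attach_um) next  # floating fragment
    exit <- which.min(dsoma)
    gd <- geodesic_dist(pts, exit)
    tip <- which.max(ifelse(is.finite(gd$dist), gd$dist, -Inf))
    span <- path_length_px(pts, gd, tip)
    # add the thinning retraction gap between skeleton end and soma surface
    len_um <- (span + max(dsoma[exit] - 1, 0)) * pixel_size_um
    if (len_um >= min_length_um) lengths <- c(lengths, len_um)
  }
  if (length(lengths) == 0) return(empty)
  list(process_count = length(lengths), lengths_um = lengths,
       total_length_um = sum(lengths), mean_length_um = mean(lengths))
}

#' Soma area
#'
#' @param soma_mask logical matrix.
#' @param pixel_size_um lateral calibration.
#' @return area in um^2 (pixel count times squared pixel size).
#' @export
soma_area <- function(soma_mask, pixel_size_um) {
  if (!any(soma_mask)) vq_stop("empty soma mask", "vq_empty_mask")
  sum(soma_mask) * pixel_size_um^2
}

#' Count intracellular puncta and call marker positivity
#'
#' Thresholds the puncta channel (maximum entropy, restricted to the cell
#' mask), keeps 8-connected bright components inside the configured area
#' band, and counts them. A cell is positive when the count exceeds
#' `count_threshold` — strictly more than two puncta for CD68 by default,
#' so 3 puncta are positive and 2 are not.
#'
#' @param cell_mask logical matrix.
#' @param puncta_img 2D puncta-channel image, aligned with the mask.
#' @param pixel_size_um lateral calibration.
#' @param config an [analysis_config()].
#' @param count_threshold puncta count that must be exceeded; defaults to
#'   `config$cd68_count_threshold`.
#' @return list with `puncta_count` and `positive`.
#' @export
puncta_positivity <- function(cell_mask, puncta_img, pixel_size_um,
                              config = analysis_config(),
                              count_threshold = config$cd68_count_threshold) {
  if (!any(cell_mask)) vq_stop("empty cell mask", "vq_empty_mask")
  vals <- puncta_img[cell_mask]
  if (length(unique(vals)) < 2) {
    return(list(puncta_count = 0L, positive = 0L > count_threshold))
  }
  thr <- max_entropy_threshold(vals, config$n_bins)
  bw <- (puncta_img > thr) & cell_mask
  lab <- label8(bw)
  comp <- component_table(lab)
  areas <- comp$n_px * pixel_size_um^2
  count <- sum(areas >= config$puncta_area_um2[1] &
               areas <= config$puncta_area_um2[2])
  list(puncta_count = as.integer(count),
       positive = count > count_threshold)
}

#' Pericyte coverage of the vessel surface
#'
#' Percent of the vessel-surface mask overlapped by the pericyte-marker
#' mask.
#'
#' @param marker_mask logical matrix (e.g. PDGFRB-positive area).
#' @param vessel_surface_mask logical matrix (e.g. lectin-positive vessel
#'   surface).
#' @return percentage in `[0, 100]`.
#' @export
pericyte_coverage <- function(marker_mask, vessel_surface_mask) {
  stopifnot(identical(dim(marker_mask), dim(vessel_surface_mask)))
  if (!any(vessel_surface_mask)) {
    vq_stop("empty vessel surface mask", "vq_empty_mask")
  }
  100 * sum(marker_mask & vessel_surface_mask) / sum(vessel_surface_mask)
}

#' Process-tip motility in a registered time-lapse
#'
#' Detects process tips (skeleton endpoints of the thresholded reporter
#' channel) in every frame, links them across frames by nearest neighbour
#' within a per-interval gate, and reports each trajectory's mean step in
#' um per frame. Tips inside or immediately around a soma are discarded
#' when soma centers are supplied, so stationary process roots and the
#' soma's own skeleton do not dilute the estimate.
#'
#' @param frames registered single-channel time-lapse, 3D `(t, y, x)`
#'   array (use [register_translation()] first if frames jitter).
#' @param pixel_size_um lateral calibration.
#' @param config an [analysis_config()]; supplies the linking gate.
#' @param soma_centers optional matrix of `(y, x)` soma centers.
#' @param soma_exclude_um radius around each soma center within which
#'   endpoints are ignored.
#' @return data frame, one row per tracked tip: `tip, cell, n_steps,
#'   mean_step_um`; `cell` is the nearest soma (or `NA`). The per-cell
#'   summary (mean over its tips) is attached as attribute `per_cell`.
#' @export
process_motility <- function(frames, pixel_size_um,
                             config = analysis_config(),
                             soma_centers = NULL, soma_exclude_um = 5) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] >= 2)
  nt <- dim(frames)[1]
  gate_px <- config$tip_gate_um_per_frame / pixel_size_um
  tips <- lapply(seq_len(nt), function(t) {
    fr <- matrix(frames[t, , ], dim(frames)[2], dim(frames)[3])
    thr <- max_entropy_threshold(fr, config$n_bins)
    ep <- skeleton_endpoints(skeletonize(fr > thr))
    if (!is.null(soma_centers) && nrow(ep) > 0) {
      keep <- rep(TRUE, nrow(ep))
      for (j in seq_len(nrow(soma_centers))) {
        d <- sqrt((ep[, 1] - soma_centers[j, 1])^2 +
                  (ep[, 2] - soma_centers[j, 2])^2) * pixel_size_um
        keep <- keep & d > soma_exclude_um
      }
      ep <- ep[keep, , drop = FALSE]
    }
    ep
  })
  if (nrow(tips[[1]]) == 0) vq_stop("no process tips detected", "vq_no_tips")
  # greedy nearest-neighbour linking, trajectories seeded at frame 1
  pos <- tips[[1]]
  n_traj <- nrow(pos)
  steps <- vector("list", n_traj)
  alive <- rep(TRUE, n_traj)
  for (t in 2:nt) {
    nxt <- tips[[t]]
    taken <- rep(FALSE, nrow(nxt))
    for (i in order(!alive)) {           # live trajectories first
      if (!alive[i] || nrow(nxt) == 0) next
      d <- sqrt((nxt[, 1] - pos[i, 1])^2 + (nxt[, 2] - pos[i, 2])^2)
      d[taken] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= gate_px) {
        steps[[i]] <- c(steps[[i]], d[j] * pixel_size_um)
        pos[i, ] <- nxt[j, ]
        taken[j] <- TRUE
      } else {
        alive[i] <- FALSE
      }
    }
  }
  cell_of <- function(p) {
    if (is.null(soma_centers)) return(NA_integer_)
    which.min((soma_centers[, 1] - p[1])^2 + (soma_centers[, 2] - p[2])^2)
  }
  out <- data.frame(
    tip = seq_len(n_traj),
    cell = vapply(seq_len(n_traj), function(i) cell_of(tips[[1]][i, ]),
                  integer(1)),
    n_steps = vapply(steps, length, integer(1)),
    mean_step_um = vapply(steps, function(s)
      if (length(s)) mean(s) else NA_real_, numeric(1))
  )
  tracked <- out[out$n_steps > 0, , drop = FALSE]
  per_cell <- if (nrow(tracked) > 0 && !all(is.na(tracked$cell))) {
    do.call(rbind, lapply(split(tracked, tracked$cell), function(d)
      data.frame(cell = d$cell[1], n_tips = nrow(d),
                 mean_step_um = mean(d$mean_step_um))))
  } else {
    data.frame(cell = integer(0), n_tips = integer(0),
               mean_step_um = numeric(0))
  }
  rownames(per_cell) <- NULL
  attr(out, "per_cell") <- per_cell
  out
}
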