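#' Scene configuration for the synthetic two-photon generator
#'
#' Describes one synthetic cortical field: straight capillary-scale vessels,
#' ramified microglia placed at controlled edge-to-edge gap distances from
#' the nearest vessel surface, an extravascular leak halo per dextran
#' channel, optional intracellular puncta, and a Poisson + Gaussian noise
#' model. Every stochastic element draws from named substreams of `seed`,
#' so a given configuration renders bit-identically.
#'
#' Geometry conventions: arrays are indexed `(z, y, x)` with 1-based pixel
#' centers; vessels run along x; microglia somata sit in the central focal
#' plane, with processes fanning away from the vessel so the soma edge
#' defines the cell-to-vessel gap.
#'
#' @param field_size_px `(ny, nx)` field size in pixels.
#' @param n_z number of focal planes.
#' @param pixel_size_um lateral calibration (default 0.254 um/px, the
#'   two-photon acquisition setting).
#' @param z_step_um axial step (default 2 um).
#' @param n_vessels number of parallel vessels, evenly spaced in y.
#' @param vessel_radius_um vessel radius (default 3 um, capillary scale).
#' @param cell_gaps_um numeric vector, one entry per microglia: the true
#'   edge-to-edge distance (um) from the soma surface to the nearest vessel
#'   surface; 0 means touching.
#' @param soma_radius_um soma radius, um.
#' @param n_processes processes per cell.
#' @param process_length_um process length from the soma surface, um.
#' @param process_spread_deg half-angle of the process fan around the
#'   direction pointing away from the vessel.
#' @param leak_fraction named vector, channel label -> fraction in `[0, 1]`
#'   of the intravascular integrated intensity that appears as an
#'   extravascular halo (e.g. `c(dextran10 = 0.3, dextran70 = 0)`).
#' @param halo_length_um exponential length constant of the leak halo.
#' @param puncta_per_cell integer (scalar or per-cell) count of CD68-like
#'   puncta rendered inside each soma; a `cd68` channel is emitted when any
#'   count is positive.
#' @param aqp4_puncta_per_cell same, for an `aqp4` channel.
#' @param vessel_intensity,soma_intensity,process_intensity,puncta_intensity
#'   rendered intensities (arbitrary units).
#' @param background constant background level added to every channel.
#' @param noise list with `poisson_gain` (photons per intensity unit; 0
#'   disables shot noise) and `gaussian_sd` (read-noise sd; 0 disables).
#'   Both off by default; see [default_noise()].
#' @param seed root seed for this scene.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(field_size_px = c(256, 256),
                         n_z = 5,
                         pixel_size_um = 0.254,
                         z_step_um = 2,
                         n_vessels = 1,
                         vessel_radius_um = 3,
                         cell_gaps_um = numeric(0),
                         soma_radius_um = 3,
                         n_processes = 4,
                         process_length_um = 10,
                         process_spread_deg = 40,
                         leak_fraction = c(dextran10 = 0, dextran40 = 0,
                                           dextran70 = 0),
                         halo_length_um = 10,
                         puncta_per_cell = 0L,
                         aqp4_puncta_per_cell = 0L,
                         vessel_intensity = 1000,
                         soma_intensity = 800,
                         process_intensity = 500,
                         puncta_intensity = 1500,
                         background = 20,
                         noise = list(poisson_gain = 0, gaussian_sd = 0),
                         seed = 1L) {
  if (any(field_size_px <= 0) || n_z <= 0 || pixel_size_um <= 0 ||
      z_step_um <= 0 || vessel_radius_um <= 0 || soma_radius_um <= 0) {
    vq_stop("all scene dimensions and calibrations must be positive",
            "vq_bad_scene_config")
  }
  if (is.null(names(leak_fraction)) || any(names(leak_fraction) == "")) {
    vq_stop("leak_fraction must be a named vector (channel -> fraction)",
            "vq_bad_scene_config")
  }
  if (any(leak_fraction < 0) || any(leak_fraction > 1)) {
    vq_stop("leak fractions must lie in [0, 1]", "vq_bad_leak_fraction")
  }
  if (any(cell_gaps_um < 0)) {
    vq_stop("cell gaps must be nonnegative", "vq_bad_scene_config")
  }
  n_cells <- length(cell_gaps_um)
  cfg <- structure(list(
    field_size_px = as.integer(field_size_px),
    n_z = as.integer(n_z),
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    n_vessels = as.integer(n_vessels),
    vessel_radius_um = vessel_radius_um,
    cell_gaps_um = as.numeric(cell_gaps_um),
    soma_radius_um = soma_radius_um,
    n_processes = as.integer(n_processes),
    process_length_um = process_length_um,
    process_spread_deg = process_spread_deg,
    leak_fraction = leak_fraction,
    halo_length_um = halo_length_um,
    puncta_per_cell = rep_len(as.integer(puncta_per_cell), max(n_cells, 1)),
    aqp4_puncta_per_cell = rep_len(as.integer(aqp4_puncta_per_cell),
                                   max(n_cells, 1)),
    vessel_intensity = vessel_intensity,
    soma_intensity = soma_intensity,
    process_intensity = process_intensity,
    puncta_intensity = puncta_intensity,
    background = background,
    noise = noise,
    seed = as.integer(seed)
  ), class = "scene_config")
  place_cells(cfg)  # placement feasibility check; errors if cells don't fit
  cfg
}

#' Default acquisition noise model
#'
#' Shot-noise-limited detection (Poisson with one photon per intensity
#' unit) plus moderate Gaussian read noise, the regime of GaAsP detectors
#' at typical two-photon laser power.
#' @return list usable as the `noise` field of [scene_config()].
#' @export
default_noise <- function() list(poisson_gain = 1, gaussian_sd = 20)

# --- geometry ---------------------------------------------------------------

# Vessel axis y positions (px, numeric) for a config.
vessel_y_positions <- function(cfg) {
  ny <- cfg$field_size_px[1]
  (seq_len(cfg$n_vessels) / (cfg$n_vessels + 1)) * ny
}

# Deterministic placement of cells along the vessels. Cells alternate sides
# of their vessel and are spaced in x so that somata and process fans do not
# overlap. Errors when a requested placement does not fit in the field.
place_cells <- function(cfg) {
  m <- length(cfg$cell_gaps_um)
  if (m == 0) {
    return(data.frame(cell = integer(0), vessel = integer(0),
                      side = integer(0), x_px = numeric(0), y_px = numeric(0),
                      gap_um = numeric(0)))
  }
  ps <- cfg$pixel_size_um
  ny <- cfg$field_size_px[1]; nx <- cfg$field_size_px[2]
  vy <- vessel_y_positions(cfg)
  reach_um <- cfg$soma_radius_um + cfg$process_length_um
  spread <- cfg$process_spread_deg * pi / 180
  x_extent_px <- (reach_um * sin(spread) + cfg$soma_radius_um) / ps
  spacing_px <- 2 * x_extent_px + 4
  vessel_of <- ((seq_len(m) - 1) %% cfg$n_vessels) + 1L
  side <- ifelse((((seq_len(m) - 1) %/% cfg$n_vessels) %% 2) == 0, 1L, -1L)
  # slot index within each (vessel, side) lane
  lane <- paste(vessel_of, side)
  slot <- stats::ave(seq_len(m), lane, FUN = seq_along)
  x_px <- x_extent_px + 2 + (slot - 1) * spacing_px
  y_px <- vy[vessel_of] + side *
    (cfg$vessel_radius_um + cfg$cell_gaps_um + cfg$soma_radius_um) / ps
  y_reach_px <- y_px + side * reach_um / ps
  if (any(x_px + x_extent_px > nx) ||
      any(y_reach_px < 1) || any(y_reach_px > ny) ||
      any(y_px < 1) || any(y_px > ny)) {
    vq_stop("cell placements do not fit in the field; enlarge field_size_px or reduce gaps/process length",
            "vq_cell_fit")
  }
  data.frame(cell = seq_len(m), vessel = vessel_of, side = side,
             x_px = x_px, y_px = y_px, gap_um = cfg$cell_gaps_um)
}

# Unit direction vectors (dy, dx) of a cell's processes: a fan of
# `n_processes` rays of half-angle `spread` around the outward normal.
process_directions <- function(cfg, side) {
  np <- cfg$n_processes
  spread <- cfg$process_spread_deg * pi / 180
  ang <- if (np == 1) 0 else seq(-spread, spread, length.out = np)
  cbind(dy = side * cos(ang), dx = sin(ang))
}

# Paint value into img (matrix) for pixels within radius_px of segment
# p0-p1 (numeric (y, x), px). Values combine by max, as fluorophores
# saturate rather than add in these renderings.
draw_segment <- function(img, p0, p1, radius_px, value) {
  lo <- floor(pmin(p0, p1) - radius_px - 1)
  hi <- ceiling(pmax(p0, p1) + radius_px + 1)
  ys <- max(1, lo[1]):min(nrow(img), hi[1])
  xs <- max(1, lo[2]):min(ncol(img), hi[2])
  if (length(ys) == 0 || length(xs) == 0) return(img)
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 == 0) {
    d2 <- (yy - p0[1])^2 + (xx - p0[2])^2
  } else {
    t <- ((yy - p0[1]) * v[1] + (xx - p0[2]) * v[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (yy - (p0[1] + t * v[1]))^2 + (xx - (p0[2] + t * v[2]))^2
  }
  sel <- d2 <= radius_px^2
  sub <- img[ys, xs]
  sub[sel] <- pmax(sub[sel], value)
  img[ys, xs] <- sub
  img
}

# Noise-free rendering of all channels. `process_extension_um` lengthens
# every process of the selected cells (vector recycled over cells), which is
# how the time-lapse generator animates tip growth.
render_scene <- function(cfg, process_extension_um = 0) {
  ny <- cfg$field_size_px[1]; nx <- cfg$field_size_px[2]
  nz <- cfg$n_z; ps <- cfg$pixel_size_um
  z_um <- (seq_len(nz) - 1) * cfg$z_step_um
  zc_idx <- ceiling(nz / 2)
  zc_um <- z_um[zc_idx]
  vy <- vessel_y_positions(cfg)

  # distance (um) from each (z, y) to the nearest vessel axis; constant in x
  d_axis <- matrix(Inf, nz, ny)
  for (y0 in vy) {
    dy2 <- ((seq_len(ny) - y0) * ps)^2
    dz2 <- (z_um - zc_um)^2
    d <- sqrt(outer(dz2, dy2, `+`))
    d_axis <- pmin(d_axis, d)
  }
  in_tube <- d_axis <= cfg$vessel_radius_um
  d_wall <- pmax(d_axis - cfg$vessel_radius_um, 0)

  # dextran channels: background + tube + leak halo scaled so that the
  # integrated extravascular intensity is exactly leak_fraction times the
  # integrated intravascular intensity
  halo <- exp(-d_wall / cfg$halo_length_um)
  halo[in_tube] <- 0
  sum_in <- sum(in_tube) * nx * cfg$vessel_intensity
  sum_halo <- sum(halo) * nx
  channels <- list()
  for (ch in names(cfg$leak_fraction)) {
    f <- cfg$leak_fraction[[ch]]
    plane <- matrix(cfg$background, nz, ny)
    plane[in_tube] <- plane[in_tube] + cfg$vessel_intensity
    if (f > 0) plane <- plane + (f * sum_in / sum_halo) * halo
    channels[[ch]] <- array(plane, dim = c(nz, ny, nx))
  }

  # microglia reporter channel
  cells <- place_cells(cfg)
  m <- nrow(cells)
  ext <- rep_len(process_extension_um, max(m, 1))
  green <- array(cfg$background, dim = c(nz, ny, nx))
  proc_truth <- NULL
  tip_truth <- NULL
  r_s_px <- cfg$soma_radius_um / ps
  if (m > 0) {
    for (j in seq_len(m)) {
      yc <- cells$y_px[j]; xc <- cells$x_px[j]
      # soma: sphere of radius soma_radius_um about (zc, yc, xc)
      for (iz in seq_len(nz)) {
        dz2 <- (z_um[iz] - zc_um)^2
        if (dz2 > cfg$soma_radius_um^2) next
        r_plane_px <- sqrt(cfg$soma_radius_um^2 - dz2) / ps
        green[iz, , ] <- draw_segment(matrix(green[iz, , ], ny, nx),
                                      c(yc, xc), c(yc, xc),
                                      r_plane_px, cfg$soma_intensity)
      }
      # processes: straight tubes in the central plane, from the soma
      # surface outward, away from the vessel
      dirs <- process_directions(cfg, cells$side[j])
      plane <- matrix(green[zc_idx, , ], ny, nx)
      for (k in seq_len(cfg$n_processes)) {
        len <- cfg$process_length_um + ext[j]
        p0 <- c(yc, xc) + dirs[k, ] * r_s_px
        p1 <- c(yc, xc) + dirs[k, ] * (r_s_px + len / ps)
        plane <- draw_segment(plane, p0, p1, 1.0, cfg$process_intensity)
        proc_truth <- rbind(proc_truth, data.frame(
          cell = j, process = k, length_um = len,
          tip_y_px = p1[1], tip_x_px = p1[2]))
      }
      green[zc_idx, , ] <- plane
    }
  }
  channels[["microglia"]] <- green

  # puncta channels (CD68-like, AQP4-like): small bright blobs in somata
  for (spec in list(c("cd68", "puncta_per_cell"),
                    c("aqp4", "aqp4_puncta_per_cell"))) {
    counts <- cfg[[spec[2]]]
    if (m > 0 && any(counts[seq_len(m)] > 0)) {
      pts <- with_local_seed(
        substream_seed(cfg$seed, paste0("puncta-", spec[1])),
        puncta_positions(cells, counts[seq_len(m)], r_s_px))
      img <- array(cfg$background, dim = c(nz, ny, nx))
      plane <- matrix(img[zc_idx, , ], ny, nx)
      if (nrow(pts) > 0) {
        for (q in seq_len(nrow(pts))) {
          plane <- draw_segment(plane, c(pts$y_px[q], pts$x_px[q]),
                                c(pts$y_px[q], pts$x_px[q]),
                                1.2, cfg$puncta_intensity)
        }
      }
      img[zc_idx, , ] <- plane
      channels[[spec[1]]] <- img
    }
  }

  list(channels = channels, cells = cells, processes = proc_truth,
       zc_idx = zc_idx, vy = vy)
}

# Rejection-sampled puncta centers inside each soma, >= 3.2 px apart so
# each punctum survives thresholding as its own connected component.
puncta_positions <- function(cells, counts, r_s_px) {
  out <- NULL
  r_in <- max(r_s_px - 2.5, 1)
  for (j in seq_len(nrow(cells))) {
    k <- counts[j]
    if (k == 0) next
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(pts) < k && tries < 2000) {
      tries <- tries + 1
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * r_in
      p <- c(cells$y_px[j] + rad * sin(ang), cells$x_px[j] + rad * cos(ang))
      if (nrow(pts) == 0 || min(sqrt(rowSums((pts - rep(p, each = nrow(pts)))^2))) > 3.2) {
        pts <- rbind(pts, p)
      }
    }
    if (nrow(pts) < k) {
      vq_stop("could not place puncta with required separation; reduce count or enlarge soma",
              "vq_puncta_fit")
    }
    out <- rbind(out, data.frame(cell = j, y_px = pts[, 1], x_px = pts[, 2]))
  }
  if (is.null(out)) {
    out <- data.frame(cell = integer(0), y_px = numeric(0), x_px = numeric(0))
  }
  out
}

# Poisson shot noise + Gaussian read noise, clamped at zero.
apply_noise <- function(x, noise) {
  if (noise$poisson_gain > 0) {
    x[] <- stats::rpois(length(x), pmax(x, 0) * noise$poisson_gain) /
      noise$poisson_gain
  }
  if (noise$gaussian_sd > 0) {
    x[] <- x + stats::rnorm(length(x), 0, noise$gaussian_sd)
  }
  pmax(x, 0)
}

#' Generate one synthetic scene with ground truth
#'
#' Renders the configured vessels, microglia, leak halos and puncta into a
#' calibrated multi-channel stack and returns it together with the exact
#' geometry used, so downstream measurements can be scored against truth.
#' The integrated extravascular halo intensity in each dextran channel
#' equals `leak_fraction` times the integrated intravascular intensity by
#' construction.
#'
#' @param config a [scene_config()].
#' @param contact_gap_um gap threshold (um) used to record the ground-truth
#'   contact flag (`gap < contact_gap_um`; strict, matching the classifier).
#' @return list with elements `stack` ([image_stack()]) and `truth`
#'   (class `ground_truth`: `$vessels`, `$cells` — including `gap_um` and
#'   `contact` —, `$processes`, `$leak_fraction`, `$puncta`).
#' @export
generate_scene <- function(config, contact_gap_um = 1) {
  stopifnot(inherits(config, "scene_config"))
  r <- render_scene(config)
  chans <- r$channels
  arr <- array(0, dim = c(length(chans), config$n_z,
                          config$field_size_px[1], config$field_size_px[2]))
  nz <- config$n_z
  noisy <- with_local_seed(substream_seed(config$seed, "noise"), {
    lapply(chans, apply_noise, noise = config$noise)
  })
  for (i in seq_along(noisy)) arr[i, , , ] <- noisy[[i]]
  stack <- image_stack(arr, config$pixel_size_um, config$z_step_um,
                       names(chans))
  m <- nrow(r$cells)
  truth <- structure(list(
    vessels = data.frame(vessel = seq_len(config$n_vessels),
                         y_px = r$vy,
                         z_index = r$zc_idx,
                         radius_um = config$vessel_radius_um),
    cells = cbind(r$cells,
                  contact = r$cells$gap_um < contact_gap_um,
                  z_index = rep(r$zc_idx, m),
                  soma_radius_um = rep(config$soma_radius_um, m),
                  puncta_count = config$puncta_per_cell[seq_len(m)],
                  aqp4_puncta_count = config$aqp4_puncta_per_cell[seq_len(m)]),
    processes = r$processes,
    leak_fraction = config$leak_fraction,
    config = config
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Generate a registered-jitter time-lapse with moving process tips
#'
#' All frames share one scene. Frame-to-frame translation jitter is applied
#' as recorded integer shifts (frame 1 is the reference), and every process
#' of every cell elongates by `motility_um_per_frame` per frame so tips
#' trace known trajectories. The exact shifts and per-frame tip
#' displacements are returned as ground truth.
#'
#' @param config a [scene_config()].
#' @param n_frames number of frames (>= 2).
#' @param jitter_px maximum absolute frame shift, px (integer shifts drawn
#'   uniformly from `[-jitter_px, jitter_px]`).
#' @param motility_um_per_frame tip displacement per frame interval, um;
#'   scalar or one value per cell.
#' @return list with `stack` (time-lapse [image_stack()]) and `truth`
#'   (adds `$shifts` with the applied `(dy, dx)` per frame and `$tips` with
#'   each cell's per-frame tip step in um).
#' @export
generate_timelapse <- function(config, n_frames, jitter_px = 0,
                               motility_um_per_frame = 0) {
  stopifnot(inherits(config, "scene_config"))
  if (n_frames < 2) vq_stop("a time-lapse needs at least 2 frames",
                            "vq_bad_timelapse")
  if (jitter_px >= min(config$field_size_px) / 2) {
    vq_stop("jitter exceeds half the field size", "vq_bad_timelapse")
  }
  m <- length(config$cell_gaps_um)
  mot <- rep_len(motility_um_per_frame, max(m, 1))
  shifts <- with_local_seed(substream_seed(config$seed, "jitter"), {
    data.frame(
      frame = seq_len(n_frames),
      dy = c(0L, if (jitter_px > 0)
        sample(-jitter_px:jitter_px, n_frames - 1, TRUE) else
          rep(0L, n_frames - 1)),
      dx = c(0L, if (jitter_px > 0)
        sample(-jitter_px:jitter_px, n_frames - 1, TRUE) else
          rep(0L, n_frames - 1)))
  })
  base <- NULL
  frames <- with_local_seed(substream_seed(config$seed, "noise"), {
    lapply(seq_len(n_frames), function(t) {
      r <- render_scene(config, process_extension_um = (t - 1) * mot)
      if (t == 1) base <<- r
      lapply(r$channels, function(ch) {
        for (iz in seq_len(config$n_z)) {
          ch[iz, , ] <- shift_int(matrix(ch[iz, , ],
                                         config$field_size_px[1],
                                         config$field_size_px[2]),
                                  shifts$dy[t], shifts$dx[t],
                                  fill = config$background)
        }
        apply_noise(ch, config$noise)
      })
    })
  })
  # max-project each frame's channels to 2D and assemble (c, t, y, x)
  ch_names <- names(frames[[1]])
  arr <- array(0, dim = c(length(ch_names), n_frames,
                          config$field_size_px[1], config$field_size_px[2]))
  for (t in seq_len(n_frames)) {
    for (i in seq_along(ch_names)) {
      arr[i, t, , ] <- apply(frames[[t]][[i]], c(2, 3), max)
    }
  }
  stack <- image_stack(arr, config$pixel_size_um, channels = ch_names,
                       time = TRUE)
  truth <- structure(list(
    vessels = data.frame(vessel = seq_len(config$n_vessels),
                         y_px = base$vy, z_index = base$zc_idx,
                         radius_um = config$vessel_radius_um),
    cells = base$cells,
    processes = base$processes,
    shifts = shifts,
    tips = if (m > 0) data.frame(cell = seq_len(m),
                                 step_um_per_frame = mot[seq_len(m)],
                                 path_length_um = (n_frames - 1) * mot[seq_len(m)])
           else data.frame(cell = integer(0), step_um_per_frame = numeric(0),
                           path_length_um = numeric(0)),
    leak_fraction = config$leak_fraction,
    config = config
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}
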