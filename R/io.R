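# Scene serialization: one multi-page 32-bit float TIFF per channel,
# ground truth as CSV sidecars, and a YAML echo of the configuration and
# calibration. TIFF samples are stored as intensity / 65535 to stay inside
# the writer's [0, 1] float convention; the scale is recorded in the YAML.

.tiff_scale <- 65535

#' Write a scene to a directory
#'
#' @param scene result of [generate_scene()] or [generate_timelapse()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack <- scene$stack
  d <- dim(stack$data)
  for (i in seq_along(stack$channels)) {
    pages <- lapply(seq_len(d[2]), function(z) {
      matrix(stack$data[i, z, , ] / .tiff_scale, d[3], d[4])
    })
    tiff::writeTIFF(pages, file.path(dir, paste0(stack$channels[i], ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  meta <- list(
    channels = stack$channels,
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    time = stack$time,
    intensity_scale = .tiff_scale,
    config = if (!is.null(scene$truth$config))
      lapply(unclass(scene$truth$config), function(x)
        if (is.numeric(x) || is.integer(x)) as.vector(x) else x)
  )
  yaml::write_yaml(meta, file.path(dir, "scene.yaml"))
  tr <- scene$truth
  for (nm in c("vessels", "cells", "processes", "shifts", "tips")) {
    if (!is.null(tr[[nm]]) && nrow(tr[[nm]]) > 0) {
      utils::write.csv(tr[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.csv(
    data.frame(channel = names(tr$leak_fraction),
               leak_fraction = as.numeric(tr$leak_fraction)),
    file.path(dir, "leak_fraction.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a scene directory back into an image stack
#'
#' @param dir directory written by [write_scene()].
#' @return list with `stack` and `truth` (the CSV sidecars that are
#'   present; `NULL` fields otherwise).
#' @export
read_scene <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  chans <- unlist(meta$channels)
  pages1 <- tiff::readTIFF(file.path(dir, paste0(chans[1], ".tif")),
                           all = TRUE)
  nz <- length(pages1); ny <- nrow(pages1[[1]]); nx <- ncol(pages1[[1]])
  arr <- array(0, dim = c(length(chans), nz, ny, nx))
  for (i in seq_along(chans)) {
    pages <- if (i == 1) pages1 else
      tiff::readTIFF(file.path(dir, paste0(chans[i], ".tif")), all = TRUE)
    for (z in seq_len(nz)) arr[i, z, , ] <- pages[[z]] * meta$intensity_scale
  }
  stack <- image_stack(arr, meta$pixel_size_um,
                       if (is.null(meta$z_step_um)) NA_real_ else meta$z_step_um,
                       chans, time = isTRUE(meta$time))
  read_csv_if <- function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) utils::read.csv(p) else NULL
  }
  truth <- list(vessels = read_csv_if("vessels"),
                cells = read_csv_if("cells"),
                processes = read_csv_if("processes"),
                shifts = read_csv_if("shifts"),
                tips = read_csv_if("tips"))
  lf <- read_csv_if("leak_fraction")
  if (!is.null(lf)) truth$leak_fraction <- stats::setNames(lf$leak_fraction,
                                                           lf$channel)
  list(stack = stack, truth = truth)
}
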