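#' Multi-channel image stack
#'
#' Container for a calibrated multi-channel 3D stack (`channel, z, y, x`) or
#' time-lapse (`channel, t, y, x`). Intensities are nonnegative; calibration
#' is strictly positive; channel labels are unique.
#'
#' @param data 4D numeric array, dimensions `(channel, z_or_t, y, x)`.
#' @param pixel_size_um lateral calibration, um per pixel.
#' @param z_step_um axial step, um (ignored for time-lapses).
#' @param channels character vector of channel labels, one per slab.
#' @param time logical; `TRUE` when the second dimension indexes frames of a
#'   time-lapse rather than focal planes.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, z_step_um = NA_real_,
                        channels, time = FALSE) {
  if (length(dim(data)) != 4) {
    vq_stop("stack data must be a 4D (channel, z, y, x) array",
            "vq_bad_stack")
  }
  if (!is.numeric(pixel_size_um) || is.na(pixel_size_um) ||
      pixel_size_um <= 0 || (!time && (is.na(z_step_um) || z_step_um <= 0))) {
    vq_stop("stack calibration must be strictly positive",
            "vq_uncalibrated_stack")
  }
  if (length(channels) != dim(data)[1] || anyDuplicated(channels)) {
    vq_stop("channel labels must be unique, one per channel",
            "vq_bad_stack")
  }
  if (min(data) < 0) {
    vq_stop("stack intensities must be nonnegative", "vq_bad_stack")
  }
  structure(list(
    data = data,
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    channels = as.character(channels),
    time = isTRUE(time)
  ), class = "image_stack")
}

#' Extract one channel of a stack
#'
#' @param stack an [image_stack()].
#' @param channel channel label.
#' @return 3D array `(z_or_t, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  i <- match(channel, stack$channels)
  if (is.na(i)) {
    vq_stop(sprintf("channel '%s' not present (have: %s)", channel,
                    paste(stack$channels, collapse = ", ")),
            "vq_missing_channel")
  }
  out <- stack$data[i, , , , drop = FALSE]
  dim(out) <- dim(stack$data)[2:4]
  out
}

n_slices <- function(stack) dim(stack$data)[2]

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d %s, %d x %d px, %.3g um/px",
              d[1], paste(x$channels, collapse = ", "), d[2],
              if (x$time) "frame(s)" else "slice(s)", d[3], d[4],
              x$pixel_size_um))
  if (!x$time && !is.na(x$z_step_um)) cat(sprintf(", %g um z-step", x$z_step_um))
  cat("\n")
  invisible(x)
}
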