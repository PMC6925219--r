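#' Translation registration of a time-lapse
#'
#' Aligns every frame to the first by a rigid integer translation estimated
#' from the maximum of the circular cross-correlation (computed via FFT,
#' after mean subtraction). This corrects the lateral drift of cortical
#' time-lapses; rotation and deformation are out of scope. Out-of-field
#' pixels exposed by the correction are filled with the modal image value
#' (the background plateau), which avoids biasing later extravascular
#' means.
#'
#' @param frames single-channel time-lapse: a 3D array `(t, y, x)` or a
#'   list of equally sized matrices.
#' @param fill fill value for exposed borders; default is the modal value of
#'   the first frame.
#' @return list with `aligned` (3D array `(t, y, x)`) and `shifts` (a data
#'   frame of the estimated applied shifts `(dy, dx)` per frame; the
#'   reference frame has shift `(0, 0)`).
#' @export
register_translation <- function(frames, fill = NULL) {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 2)
    dims <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1)))) {
      vq_stop("all frames must share one shape", "vq_bad_frames")
    }
    arr <- array(0, dim = c(length(frames), dims))
    for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
    frames <- arr
  }
  if (length(dim(frames)) != 3 || dim(frames)[1] < 2) {
    vq_stop("need a (t, y, x) array with >= 2 frames", "vq_bad_frames")
  }
  nt <- dim(frames)[1]; ny <- dim(frames)[2]; nx <- dim(frames)[3]
  sds <- apply(frames, 1, stats::sd)
  if (any(sds == 0)) {
    vq_stop("constant frame: input is unregistrable", "vq_unregistrable")
  }
  ref <- matrix(frames[1, , ], ny, nx)
  if (is.null(fill)) fill <- image_mode(ref)
  Fref <- stats::fft(ref - mean(ref))
  aligned <- array(0, dim = dim(frames))
  aligned[1, , ] <- ref
  shifts <- data.frame(frame = seq_len(nt), dy = 0L, dx = 0L)
  for (t in 2:nt) {
    fr <- matrix(frames[t, , ], ny, nx)
    cc <- Re(stats::fft(Conj(Fref) * stats::fft(fr - mean(fr)),
                        inverse = TRUE))
    peak <- arrayInd(which.max(cc), dim(cc))
    dy <- peak[1] - 1L; dx <- peak[2] - 1L
    if (dy > ny / 2) dy <- dy - ny
    if (dx > nx / 2) dx <- dx - nx
    shifts$dy[t] <- dy; shifts$dx[t] <- dx
    aligned[t, , ] <- shift_int(fr, -dy, -dx, fill = fill)
  }
  list(aligned = aligned, shifts = shifts)
}

#' Maximum-intensity projection over a z range
#'
#' @param stack an [image_stack()] (z-stack, not a time-lapse).
#' @param z_range integer slice indices to project over; default all slices.
#' @return named list of 2D matrices (one per channel) with attributes
#'   `pixel_size_um` and `z_range`.
#' @export
z_project_max <- function(stack, z_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (is.null(z_range)) z_range <- seq_len(nz)
  z_range <- as.integer(z_range)
  if (length(z_range) == 0) vq_stop("empty z range", "vq_empty_z_range")
  if (any(z_range < 1 | z_range > nz)) {
    vq_stop("z range outside the stack", "vq_bad_z_range")
  }
  out <- lapply(stack$channels, function(ch) {
    a <- get_channel(stack, ch)[z_range, , , drop = FALSE]
    apply(a, c(2, 3), max)
  })
  names(out) <- stack$channels
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  attr(out, "z_range") <- z_range
  out
}

#' Select the analyzed cortical depth window
#'
#' Partitions the stack into 50-um depth sections and keeps the band
#' `window_um` below the pia (default 100-200 um, cortical layer II/III);
#' the two most superficial sections are excluded to avoid surgical-damage
#' artefacts. Slice membership is decided by slice-center depth and the
#' window is half-open `[lo, hi)`.
#'
#' @param stack an [image_stack()] z-stack.
#' @param pia_offset_um depth of the first slice below the pia, um.
#' @param window_um length-2 depth band, um.
#' @return the sub-stack restricted to the window, with the selected slice
#'   indices in attribute `z_indices`.
#' @export
select_depth_window <- function(stack, pia_offset_um = 0,
                                window_um = c(100, 200)) {
  stopifnot(inherits(stack, "image_stack"), !stack$time)
  nz <- n_slices(stack)
  depth <- pia_offset_um + (seq_len(nz) - 1) * stack$z_step_um
  if (pia_offset_um + nz * stack$z_step_um < window_um[2]) {
    vq_stop(sprintf("stack only reaches %.0f um from the pia; %.0f um needed",
                    pia_offset_um + nz * stack$z_step_um, window_um[2]),
            "vq_stack_too_shallow")
  }
  sel <- which(depth >= window_um[1] & depth < window_um[2])
  sub <- stack$data[, sel, , , drop = FALSE]
  out <- image_stack(sub, stack$pixel_size_um, stack$z_step_um,
                     stack$channels)
  attr(out, "z_indices") <- sel
  out
}
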