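#' Extract a dual-channel intensity profile
#'
#' Samples both channels at unit-pixel steps along the straight segment
#' from the presumed microglia center towards (and usually into) the
#' vessel, by nearest-pixel lookup — the ROI-line readout used to decide
#' vessel association. A segment of euclidean length `n` px yields `n + 1`
#' samples per channel.
#'
#' @param green 2D microglia-reporter channel.
#' @param red 2D vessel channel.
#' @param from,to `(y, x)` endpoints, `from` at the cell center.
#' @param pixel_size_um lateral calibration.
#' @return object of class `profile`: list with `green`, `red` (equal
#'   length numeric vectors), `pixel_size_um` and the endpoints.
#' @export
extract_profile <- function(green, red, from, to, pixel_size_um) {
  stopifnot(identical(dim(green), dim(red)))
  if (all(round(from) == round(to))) {
    vq_stop("profile endpoints coincide", "vq_bad_profile")
  }
  len <- pt_dist(from, to)
  n <- max(1L, as.integer(ceiling(len)))
  tt <- seq(0, 1, length.out = n + 1)
  ys <- pmin(pmax(round(from[1] + tt * (to[1] - from[1])), 1), nrow(green))
  xs <- pmin(pmax(round(from[2] + tt * (to[2] - from[2])), 1), ncol(green))
  idx <- cbind(ys, xs)
  structure(list(green = green[idx], red = red[idx],
                 pixel_size_um = pixel_size_um, from = from, to = to),
            class = "profile")
}

#' Classify a microglia-vessel contact from a profile
#'
#' Implements the four-step line-profile rule: (1) the profile runs from
#' the cell center to the vessel; (2) both channel intensities are read
#' along it; (3) each channel's own standard deviation is subtracted from
#' its samples, negatives clamped to zero, which makes "decreases to zero"
#' and "increases from zero" well defined; (4) the gap between the index
#' where the adjusted reporter signal first reaches zero (and stays zero
#' for at least one further step) and the index where the adjusted vessel
#' signal first rises above zero is the microglia-vessel distance. The
#' cell is vessel-associated when that gap is strictly below the contact
#' criterion — 1 um, i.e. 4 pixels at 0.254 um/px; the criterion is
#' applied in um so it survives other calibrations. A gap <= 0 (signals
#' overlap) is a contact.
#'
#' If the reporter never reaches zero but the vessel signal rises, the two
#' signals overlap all the way and the call is a contact with gap 0. If
#' the vessel signal never rises the vessel was not reached along the
#' profile and the call is no-contact with an `NA` gap. If neither event
#' occurs the profile is uninformative and an error is raised.
#'
#' @param profile a [extract_profile()] result.
#' @param config an [analysis_config()].
#' @param cell_id optional identifier copied into the result.
#' @return object of class `contact_call`: one-row data frame with
#'   `cell_id, green_zero_index, red_rise_index, gap_px, gap_um,
#'   is_contact`.
#' @export
classify_contact <- function(profile, config = analysis_config(),
                             cell_id = NA_integer_) {
  stopifnot(inherits(profile, "profile"))
  g <- pmax(profile$green - stats::sd(profile$green), 0)
  r <- pmax(profile$red - stats::sd(profile$red), 0)
  n <- length(g)
  zero_run <- which(g == 0 & c(g[-1], 0) == 0)   # zero and stays zero
  green_zero <- if (length(zero_run)) zero_run[1] else NA_integer_
  rise <- which(r > 0)
  red_rise <- if (length(rise)) rise[1] else NA_integer_
  if (is.na(green_zero) && is.na(red_rise)) {
    vq_stop("indeterminate profile: reporter never decays and vessel signal never rises",
            "vq_indeterminate_call")
  }
  if (is.na(red_rise)) {
    gap_px <- NA_integer_
    is_contact <- FALSE
  } else if (is.na(green_zero)) {
    gap_px <- 0L           # overlap along the whole profile
    is_contact <- TRUE
  } else {
    gap_px <- as.integer(red_rise - green_zero)
    is_contact <- gap_px <= 0 ||
      gap_px * profile$pixel_size_um < config$contact_gap_um
  }
  structure(data.frame(
    cell_id = cell_id,
    green_zero_index = green_zero,
    red_rise_index = red_rise,
    gap_px = gap_px,
    gap_um = gap_px * profile$pixel_size_um,
    is_contact = is_contact
  ), class = c("contact_call", "data.frame"))
}

#' Contact call for one cell against a vessel mask
#'
#' Deterministic surrogate for the manual ROI line: the profile is drawn
#' from the soma center to the nearest vessel-mask pixel and extended
#' `overshoot_px` into the vessel so the vessel-channel rise is sampled. A
#' soma center lying inside the vessel mask is called a contact with gap
#' 0.
#'
#' @param green,red projected 2D channels.
#' @param vmask a [vessel_mask()].
#' @param soma_center `(y, x)` of the cell.
#' @param config an [analysis_config()].
#' @param cell_id optional identifier.
#' @param overshoot_px how far past the vessel edge the profile reaches.
#' @return a `contact_call` (see [classify_contact()]).
#' @export
cell_contact_call <- function(green, red, vmask, soma_center,
                              config = analysis_config(),
                              cell_id = NA_integer_, overshoot_px = 6) {
  m <- vmask$mask
  ci <- round(soma_center)
  if (m[ci[1], ci[2]]) {
    return(structure(data.frame(
      cell_id = cell_id, green_zero_index = NA_integer_,
      red_rise_index = NA_integer_, gap_px = 0L, gap_um = 0,
      is_contact = TRUE), class = c("contact_call", "data.frame")))
  }
  vx <- which(m, arr.ind = TRUE)
  if (nrow(vx) == 0) vq_stop("empty vessel mask", "vq_empty_mask")
  d2 <- (vx[, 1] - soma_center[1])^2 + (vx[, 2] - soma_center[2])^2
  target <- vx[which.min(d2), ]
  dir <- (target - soma_center) / sqrt(min(d2))
  to <- pmin(pmax(target + overshoot_px * dir, 1), dim(m))
  prof <- extract_profile(green, red, soma_center, to, vmask$pixel_size_um)
  classify_contact(prof, config, cell_id)
}

#' Fraction of vessel-associated microglia in a field
#'
#' @param calls list of `contact_call`s (or a data frame with an
#'   `is_contact` column).
#' @param n_cells_in_field total microglia in the field (defaults to the
#'   number of calls).
#' @return fraction in `[0, 1]`.
#' @export
vessel_associated_fraction <- function(calls, n_cells_in_field = NULL) {
  df <- if (is.data.frame(calls)) calls else do.call(rbind, calls)
  n_calls <- nrow(df)
  if (is.null(n_cells_in_field)) n_cells_in_field <- n_calls
  if (n_calls == 0 || n_cells_in_field <= 0) {
    vq_stop("no cells in field", "vq_no_cells")
  }
  if (n_cells_in_field < n_calls) {
    vq_stop("n_cells_in_field smaller than the number of calls",
            "vq_no_cells")
  }
  sum(df$is_contact) / n_cells_in_field
}

#' Pearson colocalization of two channels
#'
#' Plain Pearson correlation of paired pixel intensities within an ROI
#' (the Coloc2-style colocalization readout). Invariant under positive
#' affine rescaling of either channel.
#'
#' @param ch1,ch2 2D images of identical shape.
#' @param roi optional logical matrix restricting the pixels used.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_coloc <- function(ch1, ch2, roi = NULL) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(ch1), ncol(ch1))
  a <- ch1[roi]; b <- ch2[roi]
  if (length(a) < 2) vq_stop("ROI needs >= 2 pixels", "vq_bad_roi")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    vq_stop("zero variance in a channel within the ROI", "vq_zero_variance")
  }
  stats::cor(a, b)
}
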