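#' Segment microglial somata and cell bodies
#'
#' Automated stand-in for manual tracing: the reporter channel is
#' thresholded by maximum entropy; morphological opening with a disc
#' (radius `open_radius_um`) removes the thin processes, leaving the
#' somata, which are labeled 8-connected and filtered by a minimum area.
#' Each cell mask is the full-threshold component containing its soma.
#'
#' @param green projected 2D reporter channel.
#' @param pixel_size_um lateral calibration.
#' @param config an [analysis_config()].
#' @param open_radius_um opening radius, um; roughly half a soma radius.
#' @param min_soma_area_um2 smallest accepted soma, um^2.
#' @return list of per-cell records: `center` (y, x), `soma_mask`,
#'   `cell_mask`, `soma_area_um2`.
#' @export
detect_somata <- function(green, pixel_size_um, config = analysis_config(),
                          open_radius_um = 1.5, min_soma_area_um2 = 10) {
  thr <- max_entropy_threshold(green, config$n_bins)
  bw <- green > thr
  r_px <- max(1L, round(open_radius_um / pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, "disc")
  opened <- ebi_bin(EBImage::opening(bw * 1, brush))
  slab <- label8(opened)
  scomp <- component_table(slab)
  scomp <- scomp[scomp$n_px * pixel_size_um^2 >= min_soma_area_um2, ,
                 drop = FALSE]
  clab <- label8(bw)
  lapply(seq_len(nrow(scomp)), function(i) {
    soma <- slab == scomp$label[i]
    cell_id <- clab[round(scomp$centroid_y[i]), round(scomp$centroid_x[i])]
    cell <- if (cell_id > 0) clab == cell_id else soma
    list(center = c(scomp$centroid_y[i], scomp$centroid_x[i]),
         soma_mask = soma, cell_mask = cell | soma,
         soma_area_um2 = sum(soma) * pixel_size_um^2)
  })
}
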