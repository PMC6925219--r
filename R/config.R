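#' Analysis configuration
#'
#' Bundles every fixed quantification parameter in one validated object so
#' each report row can be traced to the exact settings that produced it.
#' Defaults follow the standard in vivo two-photon protocol for cortical
#' imaging of microglia and vessels:
#'
#' * `min_particle_area_um2 = 40`: vessel particles below 40 um^2 are
#'   discarded after thresholding (the "40-Infinity" particle filter); the
#'   bound is inclusive.
#' * `contact_gap_um = 1`: a microglia is vessel-associated when the
#'   profile gap between the reporter-signal falloff and the vessel-signal
#'   rise is strictly below 1 um (4 pixels at 0.254 um/px).
#' * `cd68_count_threshold = 2`: a cell is CD68-positive when it contains
#'   more than two lysosomal puncta.
#' * `projection_slices = 10`, `z_step_um = 2`: ten 2-um slices go into each
#'   maximum-intensity projection.
#' * `depth_window_um = c(100, 200)`: analysis is restricted to the
#'   100-200 um band below the pia (cortical layer II/III); half-open
#'   interval, slices assigned by slice-center depth.
#' * `n_bins = 256`: histogram resolution of the maximum-entropy threshold
#'   (the 8-bit ImageJ convention).
#'
#' @param min_particle_area_um2 minimum vessel particle area kept, um^2
#'   (inclusive).
#' @param contact_gap_um contact criterion on the profile gap, um (strict
#'   "below").
#' @param cd68_count_threshold puncta count that must be exceeded for
#'   CD68 positivity.
#' @param projection_slices number of z slices per maximum-intensity
#'   projection.
#' @param z_step_um axial step between focal planes, um.
#' @param pixel_size_um lateral calibration, um per pixel.
#' @param depth_window_um analyzed depth band below the pia, um; half-open
#'   `[lo, hi)`.
#' @param reference_mode how leakage indices are normalized: `"group"`
#'   divides by the mean of the control group, `"baseline_day"` by the
#'   mean of a designated baseline session of the same series.
#' @param n_bins histogram bins for maximum-entropy thresholding.
#' @param mask_dilate_px dilation (pixels) applied to the vessel mask before
#'   the extravascular mean, to suppress border bleed.
#' @param puncta_area_um2 length-2 area band (um^2) a connected bright spot
#'   must fall in to count as a punctum.
#' @param aqp4_count_threshold puncta count that must be exceeded for the
#'   AQP4-inclusion flag (>= 1 punctum by default).
#' @param tip_gate_um_per_frame nearest-neighbour gate when linking process
#'   tips across frames, um per frame interval.
#' @param vessel_channel channel label used to build the vessel mask; the
#'   impermeant 70 kDa tracer by default so leak cannot erode the mask.
#' @param seed root seed; all stochastic components draw from named
#'   substreams of it.
#'
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(min_particle_area_um2 = 40,
                            contact_gap_um = 1,
                            cd68_count_threshold = 2L,
                            projection_slices = 10L,
                            z_step_um = 2,
                            pixel_size_um = 0.254,
                            depth_window_um = c(100, 200),
                            reference_mode = c("group", "baseline_day"),
                            n_bins = 256L,
                            mask_dilate_px = 1L,
                            puncta_area_um2 = c(0.1, 10),
                            aqp4_count_threshold = 0L,
                            tip_gate_um_per_frame = 2,
                            vessel_channel = "dextran70",
                            seed = 1L) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(
    min_particle_area_um2 > 0, contact_gap_um > 0,
    cd68_count_threshold >= 0, projection_slices >= 1,
    z_step_um > 0, pixel_size_um > 0,
    length(depth_window_um) == 2, diff(depth_window_um) > 0,
    n_bins >= 2, mask_dilate_px >= 0,
    length(puncta_area_um2) == 2, diff(puncta_area_um2) > 0,
    tip_gate_um_per_frame > 0
  )
  structure(list(
    min_particle_area_um2 = min_particle_area_um2,
    contact_gap_um = contact_gap_um,
    cd68_count_threshold = as.integer(cd68_count_threshold),
    projection_slices = as.integer(projection_slices),
    z_step_um = z_step_um,
    pixel_size_um = pixel_size_um,
    depth_window_um = depth_window_um,
    reference_mode = reference_mode,
    n_bins = as.integer(n_bins),
    mask_dilate_px = as.integer(mask_dilate_px),
    puncta_area_um2 = puncta_area_um2,
    aqp4_count_threshold = as.integer(aqp4_count_threshold),
    tip_gate_um_per_frame = tip_gate_um_per_frame,
    vessel_channel = vessel_channel,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Fingerprint of an analysis configuration
#'
#' 32-bit FNV-1a hash of the YAML rendering of the config. Every CSV row a
#' pipeline run emits carries this hash, so reports are auditable back to
#' their parameters.
#'
#' @param config an [analysis_config()].
#' @return Character scalar, eight hex digits.
#' @export
config_hash <- function(config) {
  sprintf("%08x", fnv32(yaml::as.yaml(unclass(config))))
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
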