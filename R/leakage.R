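#' Mean extravascular fluorescence
#'
#' Arithmetic mean of the dextran-channel intensity over parenchymal
#' pixels, i.e. everywhere outside the vessel mask. The mask is dilated by
#' `config$mask_dilate_px` first so partial-volume bleed at the vessel
#' border does not contaminate the parenchymal mean.
#'
#' @param image 2D dextran-channel image.
#' @param mask a [vessel_mask()] (or a logical matrix).
#' @param config an [analysis_config()].
#' @return mean intensity outside the (dilated) vessels.
#' @export
extravascular_mean <- function(image, mask, config = analysis_config()) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  stopifnot(identical(dim(image), dim(m)))
  excl <- dilate_mask(m, config$mask_dilate_px)
  if (all(excl)) {
    vq_stop("vessel mask covers the whole image: no parenchyma to measure",
            "vq_no_parenchyma")
  }
  mean(image[!excl])
}

#' Relative leakage indices against a control group
#'
#' Divides every extravascular mean by the mean of the reference
#' (control) group, so the control group's averaged index is 1.00 by
#' construction — the convention under which permeability is reported.
#'
#' @param sample_means extravascular means of the condition of interest.
#' @param reference_means extravascular means of the control group
#'   (non-empty, positive mean).
#' @return list of class `leakage_result`: `per_image` (group, mean,
#'   relative_index), `group_summary` (group, mean_index, sd_index) and
#'   `reference_mean`.
#' @export
relative_leakage <- function(sample_means, reference_means) {
  if (length(reference_means) == 0 || mean(reference_means) <= 0) {
    vq_stop("reference group must be non-empty with a positive mean",
            "vq_bad_reference")
  }
  ref <- mean(reference_means)
  per_image <- data.frame(group = "reference",
                          extravascular_mean = reference_means,
                          relative_index = reference_means / ref)
  if (length(sample_means)) {
    per_image <- rbind(per_image,
                       data.frame(group = "sample",
                                  extravascular_mean = sample_means,
                                  relative_index = sample_means / ref))
  }
  group_summary <- do.call(rbind, lapply(split(per_image, per_image$group),
    function(d) data.frame(group = d$group[1],
                           mean_index = mean(d$relative_index),
                           sd_index = stats::sd(d$relative_index))))
  rownames(group_summary) <- NULL
  structure(list(per_image = per_image, group_summary = group_summary,
                 reference_mean = ref),
            class = "leakage_result")
}

#' @export
print.leakage_result <- function(x, ...) {
  cat("<leakage_result>\n")
  print(x$group_summary)
  invisible(x)
}

#' Size-selectivity table of relative leakage by dextran size
#'
#' For each scene: project the stack, build the vessel mask from the
#' impermeant-tracer channel (`config$vessel_channel`, 70 kDa by default,
#' so leak cannot erode the mask), measure the extravascular mean of every
#' dextran channel, then normalize each dextran size by the mean of the
#' reference condition for that size.
#'
#' @param scenes list; each element has `stack` (an [image_stack()]) and is
#'   named or carries `id`.
#' @param conditions character vector of condition labels, one per scene.
#' @param config an [analysis_config()].
#' @param reference condition label of the control group.
#' @return data frame with one row per scene x dextran channel:
#'   `image_id, condition, channel, extravascular_mean, relative_index`;
#'   the per-condition mean/sd summary is attached as attribute `summary`.
#' @export
size_selectivity_table <- function(scenes, conditions,
                                   config = analysis_config(),
                                   reference = "control") {
  stopifnot(length(scenes) == length(conditions), length(scenes) > 0)
  if (!reference %in% conditions) {
    vq_stop("no scene carries the reference condition", "vq_bad_reference")
  }
  rows <- NULL
  for (i in seq_along(scenes)) {
    st <- if (!is.null(scenes[[i]]$stack)) scenes[[i]]$stack else scenes[[i]]
    if (!config$vessel_channel %in% st$channels) {
      vq_stop(sprintf("scene %d lacks the vessel channel '%s'", i,
                      config$vessel_channel), "vq_missing_channel")
    }
    proj <- z_project_max(st)
    vm <- vessel_mask(proj[[config$vessel_channel]], st$pixel_size_um, config)
    dex <- grep("^dextran", st$channels, value = TRUE)
    for (ch in dex) {
      rows <- rbind(rows, data.frame(
        image_id = if (!is.null(names(scenes)) && names(scenes)[i] != "")
          names(scenes)[i] else paste0("scene", i),
        condition = conditions[i], channel = ch,
        extravascular_mean = extravascular_mean(proj[[ch]], vm, config)))
    }
  }
  rows$relative_index <- NA_real_
  for (ch in unique(rows$channel)) {
    ref_mean <- mean(rows$extravascular_mean[rows$channel == ch &
                                             rows$condition == reference])
    if (ref_mean <= 0) {
      vq_stop(sprintf("reference mean for %s is not positive", ch),
              "vq_bad_reference")
    }
    sel <- rows$channel == ch
    rows$relative_index[sel] <- rows$extravascular_mean[sel] / ref_mean
  }
  summ <- do.call(rbind, lapply(
    split(rows, list(rows$condition, rows$channel)),
    function(d) data.frame(condition = d$condition[1], channel = d$channel[1],
                           mean_index = mean(d$relative_index),
                           sd_index = stats::sd(d$relative_index))))
  rownames(summ) <- NULL
  attr(rows, "summary") <- summ
  rows
}
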