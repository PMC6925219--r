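#' Run the full quantification pipeline over a set of scenes
#'
#' Orchestrates projection, vessel segmentation, leakage indexing, contact
#' classification, colocalization and morphometry over a manifest of
#' stacks, and writes per-image and per-group CSV reports plus a YAML run
#' log. Every report row carries the hash of the configuration that
#' produced it; with a fixed config and seed the CSV outputs are
#' byte-identical across runs.
#'
#' @param scenes named list of scenes: each element either an
#'   [image_stack()] or a list with a `stack` field (as returned by
#'   [generate_scene()] / [read_scene()]).
#' @param manifest data frame with columns `id` (matching `names(scenes)`)
#'   and `condition`; the reference condition rows form the normalization
#'   group.
#' @param config an [analysis_config()].
#' @param out_dir directory for the CSV reports and run log; created if
#'   needed.
#' @param reference condition label used for normalization.
#' @return list with `leakage` (per image x channel), `leakage_summary`,
#'   `contacts` (per cell), `fields` (per image: cell count,
#'   vessel-associated fraction, Pearson r), `morphometry` (per cell) and
#'   `out_dir`, invisibly also written as CSVs.
#' @export
run_experiment <- function(scenes, manifest, config = analysis_config(),
                           out_dir = NULL, reference = "control") {
  if (is.null(manifest) || nrow(manifest) == 0) {
    vq_stop("empty manifest: nothing to analyze", "vq_empty_manifest")
  }
  if (!all(c("id", "condition") %in% names(manifest))) {
    vq_stop("manifest needs 'id' and 'condition' columns",
            "vq_bad_manifest")
  }
  if (!all(manifest$id %in% names(scenes))) {
    vq_stop("manifest lists scenes that were not supplied",
            "vq_bad_manifest")
  }
  stacks <- lapply(manifest$id, function(id) {
    s <- scenes[[id]]
    st <- if (inherits(s, "image_stack")) s else s$stack
    if (!inherits(st, "image_stack")) {
      vq_stop(sprintf("scene '%s' is not an image stack", id),
              "vq_bad_manifest")
    }
    for (ch in c(config$vessel_channel, "microglia")) {
      if (!ch %in% st$channels) {
        vq_stop(sprintf("scene '%s' lacks required channel '%s'", id, ch),
                "vq_missing_channel")
      }
    }
    st
  })
  names(stacks) <- manifest$id
  hash <- config_hash(config)

  leakage <- size_selectivity_table(stacks, manifest$condition, config,
                                    reference = reference)
  leakage$config_hash <- hash

  contacts <- NULL
  fields <- NULL
  morpho <- NULL
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    id <- manifest$id[i]
    proj <- z_project_max(st)
    vm <- vessel_mask(proj[[config$vessel_channel]], st$pixel_size_um,
                      config)
    green <- proj[["microglia"]]
    red <- proj[[config$vessel_channel]]
    cells <- detect_somata(green, st$pixel_size_um, config)
    r_coloc <- pearson_coloc(green, red)
    calls <- NULL
    for (j in seq_along(cells)) {
      cc <- cell_contact_call(green, red, vm, cells[[j]]$center, config,
                              cell_id = j)
      calls <- rbind(calls, cc)
      tr <- trace_processes(cells[[j]]$cell_mask, cells[[j]]$soma_mask,
                            st$pixel_size_um)
      puncta <- if ("cd68" %in% st$channels) {
        puncta_positivity(cells[[j]]$cell_mask, proj[["cd68"]],
                          st$pixel_size_um, config)
      } else list(puncta_count = NA_integer_, positive = NA)
      aqp4 <- if ("aqp4" %in% st$channels) {
        puncta_positivity(cells[[j]]$cell_mask, proj[["aqp4"]],
                          st$pixel_size_um, config,
                          count_threshold = config$aqp4_count_threshold)
      } else list(positive = NA)
      morpho <- rbind(morpho, data.frame(
        image_id = id, condition = manifest$condition[i], cell_id = j,
        process_count = tr$process_count,
        total_process_length_um = tr$total_length_um,
        mean_process_length_um = tr$mean_length_um,
        soma_area_um2 = cells[[j]]$soma_area_um2,
        puncta_count = puncta$puncta_count,
        cd68_positive = puncta$positive,
        aqp4_inclusion = aqp4$positive,
        config_hash = hash))
    }
    if (!is.null(calls)) {
      calls <- data.frame(image_id = id, condition = manifest$condition[i],
                          calls, config_hash = hash)
      contacts <- rbind(contacts, calls)
    }
    fields <- rbind(fields, data.frame(
      image_id = id, condition = manifest$condition[i],
      n_cells = length(cells),
      fraction_vessel_associated = if (length(cells))
        vessel_associated_fraction(calls) else NA_real_,
      pearson_r = r_coloc,
      vessel_area_um2 = sum(vm$components$area_um2),
      config_hash = hash))
  }

  result <- list(leakage = leakage,
                 leakage_summary = cbind(attr(leakage, "summary"),
                                         config_hash = hash),
                 contacts = contacts, fields = fields, morphometry = morpho)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(leakage, file.path(out_dir, "leakage_per_image.csv"),
                     row.names = FALSE)
    utils::write.csv(result$leakage_summary,
                     file.path(out_dir, "leakage_group_summary.csv"),
                     row.names = FALSE)
    if (!is.null(contacts)) {
      utils::write.csv(contacts, file.path(out_dir, "contact_per_cell.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(fields, file.path(out_dir, "contact_per_field.csv"),
                     row.names = FALSE)
    if (!is.null(morpho)) {
      utils::write.csv(morpho, file.path(out_dir, "morphometry_per_cell.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(list(
      config = unclass(config),
      config_hash = hash,
      reference = reference,
      n_scenes = nrow(manifest),
      package_version = as.character(utils::packageVersion("vesselquant")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ), file.path(out_dir, "run_log.yaml"))
    result$out_dir <- out_dir
  }
  invisible(result)
}
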