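#!/usr/bin/env Rscript
# Microglial morphometry on rendered reference cells (process count and
# length, soma area, CD68 puncta rule) and process-tip motility on a
# jittered time-lapse after registration.

library(vesselquant)

dir.create("results", showWarnings = FALSE)
root_seed <- 20260921

## morphology + puncta
sc <- generate_scene(scene_config(
  field_size_px = c(400, 400), n_z = 3, cell_gaps_um = 5,
  process_length_um = 15, n_processes = 5, puncta_per_cell = 3,
  leak_fraction = c(dextran70 = 0), seed = root_seed))
proj <- z_project_max(sc$stack)
cell <- detect_somata(proj$microglia, sc$stack$pixel_size_um)[[1]]
tr <- trace_processes(cell$cell_mask, cell$soma_mask,
                      sc$stack$pixel_size_um)
pp <- puncta_positivity(cell$cell_mask, proj$cd68, sc$stack$pixel_size_um)
morpho <- data.frame(process_count = tr$process_count,
                     true_process_count = 5,
                     mean_process_length_um = tr$mean_length_um,
                     true_process_length_um = 15,
                     soma_area_um2 = cell$soma_area_um2,
                     true_soma_area_um2 = pi * 9,
                     puncta_count = pp$puncta_count,
                     cd68_positive = pp$positive)
write.csv(morpho, "results/04_morphometry.csv", row.names = FALSE)
print(morpho, digits = 4)

## motility under jitter, after registration
cfg <- scene_config(field_size_px = c(256, 256), cell_gaps_um = c(3, 3),
                    process_length_um = 8, leak_fraction = c(dextran70 = 0),
                    seed = root_seed + 1)
tl <- generate_timelapse(cfg, n_frames = 6, jitter_px = 5,
                         motility_um_per_frame = 0.5)
reg <- register_translation(get_channel(tl$stack, "microglia"))
mot <- process_motility(reg$aligned, cfg$pixel_size_um,
                        soma_centers = cbind(tl$truth$cells$y_px,
                                             tl$truth$cells$x_px))
per_cell <- attr(mot, "per_cell")
per_cell$true_step_um <- 0.5
write.csv(per_cell, "results/04_motility.csv", row.names = FALSE)
print(per_cell, digits = 3)
cat(sprintf("\nregistration removed the applied jitter exactly (max shift error %d px); mean tip step %.2f um/frame vs programmed 0.50\n",
            max(abs(reg$shifts$dy - tl$truth$shifts$dy),
                abs(reg$shifts$dx - tl$truth$shifts$dx)),
            mean(per_cell$mean_step_um)))
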