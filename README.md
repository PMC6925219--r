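# vesselquant

Quantification of blood-brain-barrier (BBB) leakage and microglia-vessel
interaction in multi-channel two-photon image stacks, for labs measuring
neurovascular responses to systemic inflammation in vivo.

Cortical two-photon stacks carry a microglia reporter channel and
intravascular dextran tracers of graded size (10/40/70 kDa). `vesselquant`
extracts from them:

* **Relative BBB leakage per dextran size.** Vessels are delineated on the
  impermeant 70 kDa channel by maximum-entropy (Kapur) thresholding — the
  threshold `T` maximizes `H_bg(T) + H_fg(T)`, the summed Shannon entropies
  of the normalized histogram partitions — followed by hole filling and an
  inclusive 40 um^2 particle filter. Leakage is the mean parenchymal
  (extravascular) fluorescence, indexed to the control group so controls
  average 1.00 exactly.
* **Vessel-associated microglia.** A dual-channel line profile runs from
  the soma center to the vessel; after subtracting each profile's SD and
  clamping at zero, the gap between the reporter falloff and the vessel
  rise decides contact: `gap < 1 um` (4 px at 0.254 um/px), strictly.
* **Colocalization** (Pearson r over an ROI), **morphometry**
  (skeleton-based process counts and geodesic lengths, soma areas),
  **puncta positivity** (CD68+ iff more than two puncta), **pericyte
  coverage** (% of vessel surface overlapped), and **process motility**
  (mean per-interval tip displacement in registered time-lapses).
* **A synthetic scene generator** rendering vessels, ramified microglia at
  controlled gap distances, extravascular leak halos with exact integrated
  leak fractions, puncta, frame jitter and Poisson+Gaussian noise — with
  full ground truth, so the whole chain is validated without any acquired
  data.

## Worked example

Simulate a control cohort and an inflamed cohort whose vessels leak only
the 10 kDa tracer, then quantify:

```r
library(vesselquant)

mk <- function(f10, seed) generate_scene(scene_config(
  field_size_px = c(192, 192), n_z = 3,
  leak_fraction = c(dextran10 = f10, dextran40 = 0, dextran70 = 0),
  noise = default_noise(), seed = seed))

scenes <- c(lapply(1:4, function(i) mk(0,   seed = i)),       # intact BBB
            lapply(1:4, function(i) mk(0.3, seed = 10 + i)))  # leaky to 10 kDa
names(scenes) <- paste0("img", 1:8)
conditions <- rep(c("control", "inflamed"), each = 4)

tab <- size_selectivity_table(scenes, conditions)
attr(tab, "summary")
```

```
  condition   channel mean_index  sd_index
1   control dextran10     1.0000 0.0024489
2  inflamed dextran10     1.8590 0.0014281
3   control dextran40     1.0000 0.0014434
4  inflamed dextran40     1.0020 0.0010144
5   control dextran70     1.0000 0.0011408
6  inflamed dextran70     0.9999 0.0020413
```

The control group indexes at exactly 1.00 per the normalization contract;
the inflamed group is elevated only in the 10 kDa column — a
size-selective barrier opening — while the 40 and 70 kDa tracers stay at
control levels.

Contact classification against a vessel mask:

```r
sc <- generate_scene(scene_config(
  field_size_px = c(288, 288), n_vessels = 2, n_z = 3,
  cell_gaps_um = c(0, 0.5, 2, 5), leak_fraction = c(dextran70 = 0)))
proj <- z_project_max(sc$stack)
vm   <- vessel_mask(proj$dextran70, sc$stack$pixel_size_um)
cells <- sc$truth$cells
do.call(rbind, lapply(1:4, function(j)
  cell_contact_call(proj$microglia, proj$dextran70, vm,
                    c(cells$y_px[j], cells$x_px[j]), cell_id = j)))
```

```
  cell_id green_zero_index red_rise_index gap_px gap_um is_contact
1       1               14             14      0  0.000       TRUE
2       2               14             16      2  0.508       TRUE
3       3               14             22      8  2.032      FALSE
4       4               14             34     20  5.080      FALSE
```

Cells placed 0 and 0.5 um from the vessel are called vessel-associated;
cells at 2 and 5 um are not, and the measured gaps reproduce the
configured distances to within one pixel.

The `analysis/` directory holds numbered drivers
(`01_simulate_scenes.R` ... `05_full_pipeline.R`) that run these analyses
end to end and write their tables under `results/`. The methods vignette
(`vignettes/quantifying-bbb-leakage.Rmd`) documents the models,
parameters and design choices.

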