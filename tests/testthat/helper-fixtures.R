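# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures are stored.

# Independent brute-force Kapur criterion: for every candidate split of the
# n_bins histogram, compute the two partition entropies directly from the
# normalized sub-histograms and take the argmax (smallest on ties). Kept
# deliberately naive and separate from the package implementation.
kapur_oracle <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x); w <- (hi - lo) / n_bins
  b <- pmin(floor((x - lo) / w), n_bins - 1)
  p <- tabulate(b + 1L, n_bins) / length(x)
  best <- -Inf; best_t <- NA_integer_
  for (t in 1:(n_bins - 1)) {
    Pb <- sum(p[1:t]); Pa <- sum(p[(t + 1):n_bins])
    if (Pb <= 0 || Pa <= 0) next
    qb <- p[1:t][p[1:t] > 0] / Pb
    qa <- p[(t + 1):n_bins][p[(t + 1):n_bins] > 0] / Pa
    crit <- -sum(qb * log(qb)) - sum(qa * log(qa))
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  lo + best_t * w
}

# One-vessel scene with a per-channel leak configuration; small field, fast.
leak_scene <- function(leak10 = 0, seed = 1, noise = list(poisson_gain = 0,
                                                          gaussian_sd = 0)) {
  generate_scene(scene_config(
    field_size_px = c(192, 192), n_z = 3,
    leak_fraction = c(dextran10 = leak10, dextran40 = 0, dextran70 = 0),
    seed = seed, noise = noise))
}

# Field with many microglia at design gap distances, two vessels so the
# cells fit. Returns scene plus the ground-truth gap/contact table.
contact_scene <- function(gaps_um, seed = 1,
                          noise = list(poisson_gain = 0, gaussian_sd = 0)) {
  generate_scene(scene_config(
    field_size_px = c(288, 288), n_z = 3, n_vessels = 2,
    cell_gaps_um = gaps_um, process_length_um = 10,
    leak_fraction = c(dextran70 = 0),
    seed = seed, noise = noise))
}

# Contact calls for every cell of a scene, profiles drawn from the true
# soma centers against the mask from the impermeant channel.
call_all_cells <- function(scene, config = analysis_config()) {
  proj <- z_project_max(scene$stack)
  vm <- vessel_mask(proj$dextran70, scene$stack$pixel_size_um, config)
  cells <- scene$truth$cells
  do.call(rbind, lapply(seq_len(nrow(cells)), function(j) {
    cell_contact_call(proj$microglia, proj$dextran70, vm,
                      c(cells$y_px[j], cells$x_px[j]), config, cell_id = j)
  }))
}

# Synthetic dual-channel profile with the reporter positive on samples
# 1..(g0-1) and the vessel signal rising at sample r1.
synthetic_profile <- function(g0, r1, n = 40, pixel_size_um = 0.254) {
  green <- c(rep(200, g0 - 1), rep(0, n - g0 + 1))
  red <- c(rep(0, r1 - 1), rep(200, n - r1 + 1))
  structure(list(green = green, red = red, pixel_size_um = pixel_size_um,
                 from = c(1, 1), to = c(1, n)),
            class = "profile")
}
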