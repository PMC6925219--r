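# Segment the first cell of a rendered single-cell scene.
one_cell <- function(process_length_um = 10, n_processes = 4, seed = 1,
                     soma_radius_um = 3) {
  sc <- generate_scene(scene_config(
    field_size_px = c(400, 400), n_z = 3, cell_gaps_um = 5,
    soma_radius_um = soma_radius_um,
    process_length_um = process_length_um, n_processes = n_processes,
    leak_fraction = c(dextran70 = 0), seed = seed))
  proj <- z_project_max(sc$stack)
  list(scene = sc, cell = detect_somata(proj$microglia, 0.254)[[1]],
       proj = proj)
}

test_that("process count is exact and lengths match ground truth within 5%", {
  for (L in c(10, 20)) {
    oc <- one_cell(process_length_um = L)
    tr <- trace_processes(oc$cell$cell_mask, oc$cell$soma_mask, 0.254)
    expect_equal(tr$process_count, 4L)
    expect_true(all(abs(tr$lengths_um - L) / L < 0.05))
    expect_equal(tr$total_length_um, sum(tr$lengths_um))
    expect_equal(tr$mean_length_um, mean(tr$lengths_um))
  }
})

test_that("a soma without processes yields zero processes", {
  oc <- one_cell(n_processes = 0)
  tr <- trace_processes(oc$cell$cell_mask, oc$cell$soma_mask, 0.254)
  expect_equal(tr$process_count, 0L)
  expect_equal(tr$total_length_um, 0)
  expect_error(trace_processes(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5), 1),
               class = "vq_empty_mask")
})

test_that("process lengths are invariant under translation of the cell", {
  oc <- one_cell()
  tr <- trace_processes(oc$cell$cell_mask, oc$cell$soma_mask, 0.254)
  shift <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[31:nrow(m), 26:ncol(m)] <- m[1:(nrow(m) - 30), 1:(ncol(m) - 25)]
    out
  }
  tr2 <- trace_processes(shift(oc$cell$cell_mask), shift(oc$cell$soma_mask),
                         0.254)
  expect_equal(tr2$process_count, tr$process_count)
  expect_equal(sort(tr2$lengths_um), sort(tr$lengths_um), tolerance = 1e-10)
})

test_that("soma area is calibrated pixel count and tracks the disk formula", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(soma_area(m, 0.5), 100 * 0.25)
  disk <- matrix(FALSE, 60, 60)
  disk[(row(disk) - 30)^2 + (col(disk) - 30)^2 <= (5 / 0.5)^2] <- TRUE
  expect_equal(soma_area(disk, 0.5), pi * 25, tolerance = 3 / (pi * 25))
  expect_error(soma_area(matrix(FALSE, 3, 3), 1), class = "vq_empty_mask")
  # monotone in the generator's soma radius
  a3 <- one_cell(soma_radius_um = 3)$cell$soma_area_um2
  a4 <- one_cell(soma_radius_um = 4)$cell$soma_area_um2
  expect_gt(a4, a3)
})

test_that("segmented soma area recovers the rendered soma within 5%", {
  oc <- one_cell()
  expect_lt(abs(oc$cell$soma_area_um2 - pi * 9) / (pi * 9), 0.05)
})

test_that("CD68 positivity requires strictly more than two puncta", {
  sc <- generate_scene(scene_config(
    field_size_px = c(300, 300), n_z = 3, cell_gaps_um = c(2, 2, 2),
    puncta_per_cell = c(3, 2, 0), leak_fraction = c(dextran70 = 0)))
  proj <- z_project_max(sc$stack)
  cells <- detect_somata(proj$microglia, 0.254)
  expect_length(cells, 3)
  # match detected cells to ground truth by soma center
  truth <- sc$truth$cells
  counts <- integer(3); pos <- logical(3)
  for (j in seq_along(cells)) {
    k <- which.min((truth$y_px - cells[[j]]$center[1])^2 +
                   (truth$x_px - cells[[j]]$center[2])^2)
    pp <- puncta_positivity(cells[[j]]$cell_mask, proj$cd68, 0.254)
    counts[k] <- pp$puncta_count; pos[k] <- pp$positive
  }
  expect_equal(counts, c(3L, 2L, 0L))
  expect_equal(pos, c(TRUE, FALSE, FALSE))
})

test_that("pericyte coverage is the percent of vessel surface overlapped", {
  v <- matrix(FALSE, 40, 80); v[18:22, ] <- TRUE
  expect_equal(pericyte_coverage(v, v), 100)
  m0 <- matrix(FALSE, 40, 80); m0[1:5, ] <- TRUE
  expect_equal(pericyte_coverage(m0, v), 0)
  half <- v; half[, 41:80] <- FALSE
  expect_equal(pericyte_coverage(half, v), 50, tolerance = 0.04)
  expect_error(pericyte_coverage(v, matrix(FALSE, 40, 80)),
               class = "vq_empty_mask")
})

test_that("tip motility recovers the programmed displacement and ignores jitter", {
  cfg <- scene_config(field_size_px = c(256, 256), cell_gaps_um = c(3, 3),
                      process_length_um = 8, leak_fraction = c(dextran70 = 0),
                      seed = 3)
  centers <- function(tl) cbind(tl$truth$cells$y_px, tl$truth$cells$x_px)
  static <- generate_timelapse(cfg, n_frames = 4)
  m0 <- attr(process_motility(get_channel(static$stack, "microglia"), 0.254,
                              soma_centers = centers(static)), "per_cell")
  expect_equal(m0$mean_step_um, c(0, 0))
  moving <- generate_timelapse(cfg, n_frames = 5,
                               motility_um_per_frame = 0.5)
  m1 <- attr(process_motility(get_channel(moving$stack, "microglia"), 0.254,
                              soma_centers = centers(moving)), "per_cell")
  expect_equal(m1$mean_step_um, c(0.5, 0.5), tolerance = 0.1 / 0.5)
  # same movement program under jitter, after registration
  jittered <- generate_timelapse(cfg, n_frames = 5, jitter_px = 5,
                                 motility_um_per_frame = 0.5)
  reg <- register_translation(get_channel(jittered$stack, "microglia"))
  m2 <- attr(process_motility(reg$aligned, 0.254,
                              soma_centers = centers(jittered)), "per_cell")
  expect_equal(m2$mean_step_um, m1$mean_step_um, tolerance = 0.05)
})
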