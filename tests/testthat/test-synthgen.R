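test_that("scene generation is bit-exact under a fixed seed", {
  cfg <- scene_config(field_size_px = c(192, 192), cell_gaps_um = c(1, 3),
                      process_length_um = 6, puncta_per_cell = 2,
                      noise = default_noise(), seed = 11)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$cells, b$truth$cells)
  d <- generate_scene(scene_config(field_size_px = c(192, 192),
                                   cell_gaps_um = c(1, 3),
                                   process_length_um = 6,
                                   puncta_per_cell = 2,
                                   noise = default_noise(), seed = 12))
  expect_false(identical(a$stack$data, d$stack$data))
})

test_that("zero leak and no noise leave the parenchyma at exact background", {
  cfg <- scene_config(field_size_px = c(96, 96), n_z = 3)
  sc <- generate_scene(cfg)
  d70 <- get_channel(sc$stack, "dextran70")
  bg <- cfg$background
  # outside a generous dilation of the tube every voxel is background
  vy <- sc$truth$vessels$y_px
  r_px <- cfg$vessel_radius_um / cfg$pixel_size_um
  for (z in 1:3) {
    plane <- matrix(d70[z, , ], 96, 96)
    far <- abs(row(plane) - vy) > r_px + 3
    expect_true(all(plane[far] == bg))
  }
})

test_that("ground-truth contact flags are the thresholded requested gaps", {
  sc <- generate_scene(scene_config(field_size_px = c(288, 288),
                                    cell_gaps_um = c(0, 0.5, 2.0, 5.0)))
  expect_equal(sc$truth$cells$contact, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(sc$truth$cells$contact), 2L)
  expect_equal(nrow(generate_scene(scene_config())$truth$cells), 0L)
})

test_that("integrated extravascular/intravascular ratio equals the leak fraction", {
  for (f in c(0.1, 0.3, 0.8)) {
    cfg <- scene_config(field_size_px = c(128, 128), n_z = 5,
                        leak_fraction = c(dextran10 = f))
    sc <- generate_scene(cfg)
    d10 <- get_channel(sc$stack, "dextran10") - cfg$background
    vy <- sc$truth$vessels$y_px
    r_um <- cfg$vessel_radius_um
    z_um <- (0:4) * cfg$z_step_um
    zc <- z_um[sc$truth$vessels$z_index]
    d <- sqrt(outer((z_um - zc)^2, ((1:128 - vy) * cfg$pixel_size_um)^2, `+`))
    in_tube <- array(rep(d <= r_um, 128), dim = c(5, 128, 128))
    ratio <- sum(d10[!in_tube]) / sum(d10[in_tube])
    expect_lt(abs(ratio - f) / f, 0.01)
  }
})

test_that("scene configs reject invalid leak fractions and placements", {
  expect_error(scene_config(leak_fraction = c(dextran10 = -0.1)),
               class = "vq_bad_leak_fraction")
  expect_error(scene_config(leak_fraction = c(dextran10 = 1.2)),
               class = "vq_bad_leak_fraction")
  expect_error(scene_config(field_size_px = c(64, 64),
                            cell_gaps_um = c(2, 2, 2, 2, 2, 2)),
               class = "vq_cell_fit")
})

test_that("time-lapse ground truth records exact shifts and tip paths", {
  cfg <- scene_config(field_size_px = c(256, 256), cell_gaps_um = c(3, 3),
                      process_length_um = 8, seed = 5)
  # no jitter, no motility: frames identical
  tl0 <- generate_timelapse(cfg, n_frames = 3)
  expect_identical(tl0$stack$data[, 1, , ], tl0$stack$data[, 3, , ])
  # motility 0.5 um/frame over 5 frames: cumulative tip path 2.0 um
  tl <- generate_timelapse(cfg, n_frames = 5, motility_um_per_frame = 0.5)
  expect_equal(tl$truth$tips$path_length_um, c(2.0, 2.0))
  # jitter bounded by construction, reference frame unshifted
  tlj <- generate_timelapse(cfg, n_frames = 6, jitter_px = 4)
  expect_true(all(abs(tlj$truth$shifts$dy) <= 4))
  expect_true(all(abs(tlj$truth$shifts$dx) <= 4))
  expect_equal(unlist(tlj$truth$shifts[1, c("dy", "dx")]),
               c(dy = 0, dx = 0))
  expect_error(generate_timelapse(cfg, n_frames = 1), class = "vq_bad_timelapse")
  expect_error(generate_timelapse(cfg, n_frames = 3, jitter_px = 200),
               class = "vq_bad_timelapse")
})

test_that("scenes survive a TIFF round trip with their ground truth", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(scene_config(field_size_px = c(192, 192),
                                    cell_gaps_um = 2, process_length_um = 6,
                                    puncta_per_cell = 3))
  write_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "microglia.tif")))
  back <- read_scene(dir)
  expect_equal(back$stack$channels, sc$stack$channels)
  expect_equal(back$stack$pixel_size_um, sc$stack$pixel_size_um)
  expect_lt(max(abs(back$stack$data - sc$stack$data)), 1e-2)
  expect_equal(back$truth$cells$gap_um, sc$truth$cells$gap_um)
  expect_equal(back$truth$leak_fraction, sc$truth$leak_fraction,
               ignore_attr = FALSE)
})
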