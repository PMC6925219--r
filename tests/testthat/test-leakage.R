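test_that("extravascular mean reads the uniform background exactly", {
  sc <- leak_scene(0)
  proj <- z_project_max(sc$stack)
  vm <- vessel_mask(proj$dextran70, sc$stack$pixel_size_um)
  expect_equal(extravascular_mean(proj$dextran10, vm), 20)
  expect_equal(extravascular_mean(matrix(0, 192, 192), vm), 0)
  expect_error(extravascular_mean(proj$dextran10, matrix(TRUE, 192, 192)),
               class = "vq_no_parenchyma")
})

test_that("extravascular excess is linear in the configured leak fraction", {
  bg <- 20
  m1 <- local({
    sc <- leak_scene(0.15)
    proj <- z_project_max(sc$stack)
    vm <- vessel_mask(proj$dextran70, sc$stack$pixel_size_um)
    extravascular_mean(proj$dextran10, vm)
  })
  m2 <- local({
    sc <- leak_scene(0.30)
    proj <- z_project_max(sc$stack)
    vm <- vessel_mask(proj$dextran70, sc$stack$pixel_size_um)
    extravascular_mean(proj$dextran10, vm)
  })
  expect_equal((m2 - bg) / (m1 - bg), 2, tolerance = 1e-6)
})

test_that("relative leakage normalizes the control group to exactly 1.00", {
  res <- relative_leakage(c(3.0), c(2.0, 4.0))
  ref <- res$per_image[res$per_image$group == "reference", ]
  expect_equal(ref$relative_index, c(2 / 3, 4 / 3))
  expect_equal(res$group_summary$mean_index[
    res$group_summary$group == "reference"], 1.0)
  expect_equal(res$per_image$relative_index[
    res$per_image$group == "sample"], 1.0)   # sample mean equals reference
  self <- relative_leakage(c(5, 1, 3), c(5, 1, 3))
  expect_equal(self$group_summary$mean_index, c(1, 1))
  expect_error(relative_leakage(1, numeric(0)), class = "vq_bad_reference")
  expect_error(relative_leakage(1, c(0, 0)), class = "vq_bad_reference")
})

test_that("relative indices are invariant to a common detector gain", {
  scenes <- list(a = leak_scene(0, 1), b = leak_scene(0, 2),
                 c = leak_scene(0.3, 3))
  tab <- size_selectivity_table(scenes, c("control", "control", "lps"))
  scaled <- lapply(scenes, function(s) {
    s$stack$data <- s$stack$data * 3.7
    s
  })
  tab2 <- size_selectivity_table(scaled, c("control", "control", "lps"))
  expect_equal(tab2$relative_index, tab$relative_index, tolerance = 1e-10)
})

test_that("size-selectivity table flags only the leaking dextran size", {
  mk <- function(f10, seed) generate_scene(scene_config(
    field_size_px = c(192, 192), n_z = 3,
    leak_fraction = c(dextran10 = f10, dextran40 = 0, dextran70 = 0),
    seed = seed))
  scenes <- list(c1 = mk(0, 1), c2 = mk(0, 2), m1 = mk(0.3, 3))
  tab <- size_selectivity_table(scenes, c("control", "control", "mrl"))
  i10 <- tab$relative_index[tab$condition == "mrl" & tab$channel == "dextran10"]
  i40 <- tab$relative_index[tab$condition == "mrl" & tab$channel == "dextran40"]
  i70 <- tab$relative_index[tab$condition == "mrl" & tab$channel == "dextran70"]
  expect_gt(i10, 1.2)
  expect_equal(i40, 1.0, tolerance = 0.02)
  expect_equal(i70, 1.0, tolerance = 0.02)
  # all leak fractions zero: every index is ~1
  scenes0 <- list(c1 = mk(0, 1), c2 = mk(0, 2), m1 = mk(0, 3))
  tab0 <- size_selectivity_table(scenes0, c("control", "control", "mrl"))
  expect_equal(tab0$relative_index, rep(1, nrow(tab0)), tolerance = 1e-9)
  expect_error(size_selectivity_table(scenes, c("a", "a", "b"),
                                      reference = "control"),
               class = "vq_bad_reference")
})

test_that("relative index is monotone in leak fraction and recovers the ratio", {
  mk <- function(f, seed) leak_scene(f, seed)
  scenes <- list(c1 = mk(0, 1), c2 = mk(0, 2),
                 lo = mk(0.1, 3), hi = mk(0.3, 4))
  tab <- size_selectivity_table(scenes, c("control", "control", "lo", "hi"))
  d10 <- tab[tab$channel == "dextran10", ]
  ex <- function(cond) d10$relative_index[d10$condition == cond] - 1
  expect_true(ex("lo") > 0 && ex("hi") > ex("lo"))
  expect_lt(abs(ex("hi") / ex("lo") - 3) / 3, 0.05)
})
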