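test_that("profiles sample both channels at unit-pixel steps", {
  g <- matrix(seq_len(32 * 32), 32, 32)
  r <- g * 2
  p <- extract_profile(g, r, c(5, 5), c(5, 15), 0.254)
  expect_length(p$green, 11)           # 10 px segment -> 11 samples
  expect_length(p$red, 11)
  expect_equal(p$red, 2 * p$green)
  pc <- extract_profile(matrix(7, 8, 8), matrix(7, 8, 8), c(2, 2), c(6, 6), 1)
  expect_true(all(pc$green == 7))
  expect_error(extract_profile(g, r, c(5, 5), c(5.2, 5.1), 0.254),
               class = "vq_bad_profile")
})

test_that("profile from a rendered cell peaks at the soma and decays outward", {
  sc <- contact_scene(5)
  proj <- z_project_max(sc$stack)
  cell <- sc$truth$cells[1, ]
  vy <- sc$truth$vessels$y_px[cell$vessel]
  p <- extract_profile(proj$microglia, proj$dextran70,
                       c(cell$y_px, cell$x_px), c(vy, cell$x_px),
                       sc$stack$pixel_size_um)
  expect_equal(p$green[1], max(p$green))
  expect_lt(mean(p$green[(length(p$green) - 5):length(p$green)]), p$green[1])
})

test_that("contact verdict follows the strict 4-pixel (1 um) gap rule", {
  cfg <- analysis_config()
  c3 <- classify_contact(synthetic_profile(10, 13), cfg)   # gap 3
  expect_equal(c3$gap_px, 3L)
  expect_true(c3$is_contact)
  c4 <- classify_contact(synthetic_profile(10, 14), cfg)   # gap 4
  expect_equal(c4$gap_px, 4L)
  expect_false(c4$is_contact)
  cm2 <- classify_contact(synthetic_profile(10, 8), cfg)   # overlap
  expect_equal(cm2$gap_px, -2L)
  expect_true(cm2$is_contact)
  # verdict flips exactly between gap 3 and gap 4
  verdicts <- vapply(11:17, function(r1)
    classify_contact(synthetic_profile(10, r1), cfg)$is_contact, logical(1))
  expect_equal(verdicts, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("degenerate profiles produce the documented calls and errors", {
  flat <- structure(list(green = rep(100, 20), red = rep(0, 20),
                         pixel_size_um = 0.254, from = c(1, 1), to = c(1, 20)),
                    class = "profile")
  expect_error(classify_contact(flat), class = "vq_indeterminate_call")
  # reporter decays but the vessel is never reached: no contact, NA gap
  no_vessel <- synthetic_profile(10, 15, n = 20)
  no_vessel$red <- rep(0, 20)
  call <- classify_contact(no_vessel)
  expect_false(call$is_contact)
  expect_true(is.na(call$gap_px))
  # reporter never decays but vessel rises: overlap, contact at gap 0
  overlap <- structure(list(green = c(rep(200, 19), 180),
                            red = c(rep(0, 10), rep(200, 10)),
                            pixel_size_um = 0.254, from = c(1, 1),
                            to = c(1, 20)), class = "profile")
  ocall <- classify_contact(overlap)
  expect_true(ocall$is_contact)
  expect_equal(ocall$gap_px, 0L)
})

test_that("noise-free phantom cells at design gaps are classified perfectly", {
  sc <- contact_scene(c(0, 0.5, 2.0, 5.0))
  calls <- call_all_cells(sc)
  expect_equal(calls$is_contact, sc$truth$cells$contact)
  expect_equal(calls$is_contact, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("classification agrees with ground truth under acquisition noise", {
  withr::local_seed(99)
  agree <- 0; total <- 0
  for (s in 1:3) {
    gaps <- sample(c(0, 0.5, 2, 5), 10, TRUE)
    sc <- contact_scene(gaps, seed = 100 + s, noise = default_noise())
    calls <- call_all_cells(sc)
    agree <- agree + sum(calls$is_contact == sc$truth$cells$contact)
    total <- total + length(gaps)
  }
  expect_gte(agree / total, 0.95)
})

test_that("vessel-associated fraction is contacts over cells in field", {
  calls <- data.frame(is_contact = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(vessel_associated_fraction(calls, 10), 0.30)
  expect_equal(vessel_associated_fraction(
    data.frame(is_contact = rep(TRUE, 4))), 1.0)
  expect_error(vessel_associated_fraction(calls[0, , drop = FALSE]),
               class = "vq_no_cells")
  expect_error(vessel_associated_fraction(calls, 3), class = "vq_no_cells")
})

test_that("a field built with 20% contact cells reports a 0.20 fraction", {
  gaps <- c(0, 0.5, rep(c(2, 3, 5), length.out = 8))
  sc <- generate_scene(scene_config(field_size_px = c(480, 480), n_z = 3,
                                    n_vessels = 3, cell_gaps_um = gaps,
                                    process_length_um = 8,
                                    leak_fraction = c(dextran70 = 0)))
  calls <- call_all_cells(sc)
  frac <- vessel_associated_fraction(calls, nrow(sc$truth$cells))
  expect_equal(frac, 0.20, tolerance = 1 / length(gaps) + 1e-9)
})

test_that("Pearson colocalization behaves as a correlation", {
  withr::local_seed(21)
  a <- matrix(runif(1e4, 10, 200), 100, 100)
  expect_equal(pearson_coloc(a, a), 1)
  expect_equal(pearson_coloc(a, -2 * a + 500), -1)
  b <- matrix(runif(1e4, 10, 200), 100, 100)
  expect_lt(abs(pearson_coloc(a, b)), 0.05)
  # invariance under positive affine rescaling
  expect_equal(pearson_coloc(a, b), pearson_coloc(a * 3 + 7, b))
  roi <- matrix(FALSE, 100, 100); roi[1:10, 1:10] <- TRUE
  expect_equal(pearson_coloc(a, a, roi), 1)
  expect_error(pearson_coloc(a, matrix(5, 100, 100)),
               class = "vq_zero_variance")
})
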