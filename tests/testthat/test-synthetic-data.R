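test_that("adherent fields hit the requested coverage exactly and deterministically", {
  for (cv in c(0, 0.4, 1)) {
    sc <- gen_adherent_field(64, 64, cv, seed = 7)
    expect_equal(sc$truth$coverage_true, mean(sc$truth$mask))
    expect_equal(sc$truth$coverage_true, round(cv * 64 * 64) / (64 * 64))
    expect_lt(abs(sc$truth$coverage_true - cv), 0.01)
  }
  expect_true(all(gen_adherent_field(64, 64, 0, seed = 1)$truth$mask == FALSE))
  expect_true(all(gen_adherent_field(64, 64, 1, seed = 1)$truth$mask == TRUE))
  a <- gen_adherent_field(96, 64, 0.37, seed = 7)
  b <- gen_adherent_field(96, 64, 0.37, seed = 7)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_error(gen_adherent_field(64, 64, 1.2, seed = 1), "coverage")
})

test_that("well scans follow the requested gradient and clip at 1", {
  lay <- field_layout("six_well")
  hom <- gen_well_scan(lay, 0.5, gradient_strength = 0, seed = 2,
                       field_width = 48, field_height = 48)
  expect_length(hom$truth$per_field_coverage, 38)
  # targets identical up to per-field rounding on the 48x48 grid
  expect_true(all(abs(hom$truth$per_field_coverage - 0.5) <= 0.5 / 48^2))
  grad <- gen_well_scan(lay, 0.5, gradient_strength = 0.2, seed = 2,
                        field_width = 48, field_height = 48)
  expect_gt(o_cv_pct(grad$truth$per_field_coverage), 0)
  steep <- gen_well_scan(field_layout("one_well"), 0.9,
                         gradient_strength = 0.5, seed = 3,
                         field_width = 32, field_height = 32)
  expect_length(steep$truth$per_field_coverage, 384)
  expect_true(all(steep$truth$per_field_coverage <= 1))
})

test_that("neuro scenes respect spacing, borders and exact marker fractions", {
  sc <- gen_neuro_scene(256, 256, n_cells = 50, seed = 3)
  ctr <- sc$truth$centers
  expect_equal(nrow(ctr), 50)
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  expect_true(all(d >= 8))
  expect_true(all(ctr >= 12) &&
                all(ctr[, 1] <= 256 - 12) && all(ctr[, 2] <= 256 - 12))
  sc2 <- gen_neuro_scene(128, 128, n_cells = 20, neuron_fraction = 1,
                         th_fraction_of_neurons = 0.25, seed = 1)
  expect_equal(nrow(sc2$truth$centers), 20)
  expect_length(sc2$truth$th_positive_ids, 5)
  expect_true(all(sc2$truth$th_positive_ids %in% sc2$truth$neuron_ids))
  z <- gen_neuro_scene(64, 64, n_cells = 0, seed = 1)
  expect_true(max(z$field$pixels) <= 10)
  expect_error(gen_neuro_scene(64, 64, n_cells = 500, seed = 1), "infeasible")
})

test_that("organoid truth matches brute-force geometry", {
  d <- gen_organoid_image("disk", 50, pixel_size = 1, seed = 4)
  expect_lt(abs(d$truth$organoid_area_true - pi * 50^2) / (pi * 50^2), 0.02)
  expect_equal(d$truth$organoid_area_true, sum(d$truth$mask))
  expect_equal(d$truth$organoid_feret_true, o_feret_brute(d$truth$mask))
  # dark object on bright background
  expect_lt(mean(d$field$pixels[d$truth$mask]),
            0.4 * mean(d$field$pixels[!d$truth$mask]))
  e <- gen_organoid_image("ellipse", c(30, 18), pixel_size = 2, seed = 5)
  expect_equal(e$truth$organoid_area_true, sum(e$truth$mask) * 4)
  b <- gen_organoid_image("blob", 25, pixel_size = 1, seed = 6)
  expect_equal(b$truth$organoid_feret_true, o_feret_brute(b$truth$mask))
  expect_error(gen_organoid_image("disk", 100, seed = 1, width = 64, height = 64),
               "margin")
})

test_that("single-pixel and square masks follow the center-to-center Feret convention", {
  m1 <- matrix(FALSE, 21, 21); m1[11, 11] <- TRUE
  expect_equal(o_feret_brute(m1), 0)
  expect_equal(feret_diameter(m1), 0)
  sq <- matrix(FALSE, 21, 21); sq[6:16, 6:16] <- TRUE  # 11 px side
  expect_equal(o_feret_brute(sq), 10 * sqrt(2))
  expect_equal(feret_diameter(sq), 10 * sqrt(2))
})

test_that("dilution series are reproducible and noiseless points sit on the curve", {
  d0 <- gen_dilution_series(c(1, 2, 4, 8, 16), noise_sd = 0, seed = 9)
  expect_equal(d0$confluency_pct, 95 * (1 - exp(-0.3 * c(1, 2, 4, 8, 16))))
  d1 <- gen_dilution_series(c(1, 2, 4, 8, 16), noise_sd = 2, seed = 9)
  d2 <- gen_dilution_series(c(1, 2, 4, 8, 16), noise_sd = 2, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(d1$confluency_pct >= 0 & d1$confluency_pct <= 100))
  expect_error(gen_dilution_series(c(1, 2, 2, 8), noise_sd = 0), "increasing")
})

test_that("generated nuclei clear the segmentation threshold (feasibility)", {
  sc <- gen_neuro_scene(96, 96, n_cells = 4, seed = 11)
  d <- dog_filter(sc$field$pixels[, , 1], c(10, 2), c(60, 20))
  for (i in seq_len(4))
    expect_gt(d[round(sc$truth$centers[i, 1]), round(sc$truth$centers[i, 2])], 50)
})
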