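test_that("organoid segmentation recovers the generated mask", {
  sc <- gen_organoid_image("disk", 50, pixel_size = 1, seed = 4)
  m <- segment_organoid(sc$field)
  jac <- sum(m & sc$truth$mask) / sum(m | sc$truth$mask)
  expect_gte(jac, 0.95)
  expect_length(attr(m, "flag"), 0)
})

test_that("blank wells are flagged, and the larger of two objects wins", {
  set.seed(123)
  blank <- field_image(matrix(900, 128, 128) +
                         matrix(stats::rnorm(128^2, 0, 4), 128, 128))
  m <- segment_organoid(blank)
  expect_equal(attr(m, "flag"), "no_organoid")
  expect_false(any(m))
  img <- matrix(900, 160, 160)
  d1 <- outer((1:160 - 60)^2, (1:160 - 60)^2, "+")   # r=40 object
  d2 <- outer((1:160 - 130)^2, (1:160 - 130)^2, "+") # r=12 object
  img[d1 <= 40^2] <- 250
  img[d2 <= 12^2] <- 250
  m2 <- segment_organoid(img)
  expect_true(all(m2[d1 <= 39^2]))
  expect_false(any(m2[d2 <= 12^2]))
})

test_that("measurements follow the pixel-count and Feret conventions", {
  m <- matrix(FALSE, 30, 30)
  set.seed(2); m[sample(900, 100)] <- TRUE
  expect_equal(measure_organoid(m, 1)$area, 100)
  line <- matrix(FALSE, 5, 40); line[3, 10:30] <- TRUE  # 21 px line
  expect_equal(measure_organoid(line, 2)$feret_diameter, 40)
  sq <- matrix(FALSE, 21, 21); sq[6:16, 6:16] <- TRUE
  expect_equal(measure_organoid(sq, 1)$feret_diameter, 10 * sqrt(2))
  expect_error(measure_organoid(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("hull-based Feret equals the brute-force pairwise maximum", {
  set.seed(7)
  for (i in 1:40) {
    sc <- gen_organoid_image("blob", sample(8:20, 1), pixel_size = 1,
                             seed = 1000 + i)
    expect_equal(feret_diameter(sc$truth$mask), o_feret_brute(sc$truth$mask))
  }
  # sparse random point clouds too
  for (i in 1:20) {
    m <- matrix(FALSE, 25, 25); m[sample(625, sample(2:30, 1))] <- TRUE
    expect_equal(feret_diameter(m), o_feret_brute(m))
  }
})

test_that("measurements scale with pixel size and are rigid-motion invariant", {
  sc <- gen_organoid_image("blob", 18, pixel_size = 1, seed = 77)
  m <- sc$truth$mask
  base <- measure_organoid(m, 1)
  scaled <- measure_organoid(m, 3.25)
  expect_equal(scaled$area, base$area * 3.25^2)
  expect_equal(scaled$feret_diameter, base$feret_diameter * 3.25)
  pad <- matrix(FALSE, nrow(m) + 10, ncol(m) + 10)
  pad[6:(5 + nrow(m)), 9:(8 + ncol(m))] <- m    # translation
  expect_equal(measure_organoid(pad, 1)$feret_diameter, base$feret_diameter)
  rot <- t(m)[ncol(m):1, ]                      # 90 degree rotation
  expect_equal(measure_organoid(rot, 1)$feret_diameter, base$feret_diameter)
  expect_equal(measure_organoid(rot, 1)$area, base$area)
})

test_that("rasterized disks match their continuous area and diameter", {
  for (r in seq(10, 60, by = 10)) {
    d <- outer(-70:70, -70:70, function(a, b) a^2 + b^2) <= r^2
    mm <- measure_organoid(d, 1)
    expect_gte(mm$area / (pi * r^2), 0.97)
    expect_lte(mm$area / (pi * r^2), 1.03)
    expect_gte(mm$feret_diameter / (2 * r), 0.95)
    expect_lte(mm$feret_diameter / (2 * r), 1.02)
  }
})

test_that("per-line batch statistics match hand computations and pooling raises CV", {
  df <- data.frame(line_id = rep(c("l1", "l2"), each = 3),
                   area = c(100, 100, 100, 90, 100, 110),
                   feret = c(10, 10, 10, 9, 10, 11))
  st <- batch_stats(df)
  expect_equal(st$cv_area, c(0, 10))
  expect_equal(st$mean_area, c(100, 100))
  # two batches, each internally constant but at different levels
  pooled <- data.frame(line_id = "l1",
                       batch_id = rep(c("b1", "b2"), each = 3),
                       area = c(rep(100, 3), rep(130, 3)),
                       feret = c(rep(10, 3), rep(13, 3)))
  per_batch <- batch_stats(pooled, pool_batches = FALSE)
  expect_equal(per_batch$cv_area, c(0, 0))
  expect_gt(batch_stats(pooled, pool_batches = TRUE)$cv_area, 0)
  single <- batch_stats(data.frame(line_id = "x", area = 5, feret = 1))
  expect_true(is.na(single$cv_area))
})
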