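test_that("difference of Gaussians cancels DC and reproduces the kernel on an impulse", {
  expect_equal(dog_filter(matrix(77, 32, 32), c(10, 2), c(60, 20)),
               matrix(0, 32, 32), tolerance = 1e-10)
  img <- matrix(0, 31, 31); img[16, 16] <- 1
  got <- dog_filter(img, c(11, 1), c(11, 3))
  K <- o_kernel2d(11, 1) - o_kernel2d(11, 3)
  expect_equal(got[11:21, 11:21], K, tolerance = 1e-12)
})

test_that("kernel profiles are normalized truncated Gaussians", {
  for (sz in c(10, 11, 60, 99)) {
    g <- gauss_profile(sz, sz / 5)
    expect_equal(sum(g), 1)
    expect_equal(g, rev(g))  # symmetric sample positions, even or odd
  }
})

test_that("nuclei segmentation counts isolated and touching blobs correctly", {
  blank <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(blank$n_nuclei, 0)
  one <- matrix(0, 64, 64)
  ys <- outer((1:64 - 32)^2, (1:64 - 32)^2, "+")
  one <- 200 * exp(-ys / (2 * 16))
  seg1 <- segment_nuclei(one)
  expect_equal(seg1$n_nuclei, 1)
  # two blobs 13 px apart merge into one mask component, split into two
  # (at 12 px the distance-transform saddle depth is exactly h = 1 and the
  # h-minima transform merges the basins, by design)
  two <- matrix(0, 80, 80)
  d1 <- outer((1:80 - 40)^2, (1:80 - 34)^2, "+")
  d2 <- outer((1:80 - 40)^2, (1:80 - 47)^2, "+")
  two <- 160 * exp(-d1 / 32) + 160 * exp(-d2 / 32)
  seg2 <- segment_nuclei(two)
  merged <- label8(seg2$nuc_mask)
  expect_equal(max(merged), 1)      # single component before splitting
  expect_equal(seg2$n_nuclei, 2)    # two labels after watershed splitting
})

test_that("ROIs are disjoint supersets of their nuclei and clip at borders", {
  one <- 200 * exp(-outer((1:64 - 32)^2, (1:64 - 32)^2, "+") / 32)
  seg <- segment_nuclei(one)
  roi <- build_cell_rois(seg)
  expect_true(all(seg$nuc_labels[seg$nuc_labels > 0] ==
                    roi[seg$nuc_labels > 0]))
  expect_gt(sum(roi == 1), sum(seg$nuc_labels == 1))
  # nucleus near the border: ROI stays inside the frame (no wraparound)
  near <- 200 * exp(-outer((1:64 - 10)^2, (1:64 - 32)^2, "+") / 32)
  segn <- segment_nuclei(near)
  roin <- build_cell_rois(segn)
  expect_equal(segn$n_nuclei, 1)
  expect_true(all(which(roin > 0, arr.ind = TRUE)[, 1] <= 40))
  # two adjacent nuclei share no ROI pixel by construction of the labels
  sc <- gen_neuro_scene(96, 96, n_cells = 6, seed = 4)
  seg2 <- segment_nuclei(sc$field$pixels[, , 1])
  roi2 <- build_cell_rois(seg2)
  expect_equal(sort(unique(roi2[roi2 > 0])), seq_len(seg2$n_nuclei))
})

test_that("marker masks satisfy their clause-by-clause definition", {
  expect_false(any(segment_marker_mask(matrix(0, 64, 64), 3, 10, 50)))
  # uniform channel: the global median clause fires everywhere except the
  # four corners, where the zero-padded 3x3 window is majority-padding
  u <- segment_marker_mask(matrix(100, 64, 64), 3, 10, 50)
  expect_equal(sum(!u), 4)
  expect_false(u[1, 1] || u[1, 64] || u[64, 1] || u[64, 64])
  expect_true(all(u[2:63, 2:63]))
  # thin bright line under TH thresholds: fine DoG catches it
  line <- matrix(0, 64, 64); line[31:32, 10:54] <- 40
  m <- segment_marker_mask(line, 3, 10, 50)
  expect_gte(sum(m & line > 0) / sum(line > 0), 0.8)
  expect_false(any(median3(line) > 50))  # global clause alone misses it
})

test_that("TH-positive calling respects strict threshold semantics", {
  roi <- matrix(0L, 20, 20); roi[5:15, 5:15] <- 1L
  nuc <- roi == 1L   # nucleus fills the ROI so the TH background is exactly 0
  tuj <- matrix(TRUE, 20, 20)
  thm <- matrix(FALSE, 20, 20)
  # ROI mean of the background-subtracted TH is exactly 20 -> NOT positive
  th_exact <- matrix(0, 20, 20); th_exact[roi == 1L] <- 20
  res <- classify_cells(roi, nuc, th_exact, tuj, thm)
  expect_equal(res$cells$th_mean_bgsub, 20)
  expect_false(res$cells$is_th_positive)
  res2 <- classify_cells(roi, nuc, th_exact + (roi == 1L), tuj, thm)
  expect_true(res2$cells$is_th_positive)
  # all-zero TH channel: no positives whatever the masks say
  res0 <- classify_cells(roi, nuc, matrix(0, 20, 20), tuj, tuj)
  expect_equal(res0$n_th_positive, 0)
  expect_equal(res0$n_neurons, 1)
})

test_that("summary fractions respect their invariants on synthetic scenes", {
  sc <- gen_neuro_scene(160, 160, n_cells = 25, neuron_fraction = 0.8,
                        th_fraction_of_neurons = 0.25, seed = 8)
  res <- segment_scene(sc$field)
  expect_lte(res$n_th_positive, res$n_neurons)
  expect_lte(res$n_neurons, res$n_nuclei)
  expect_equal(res$neuron_fraction, res$n_neurons / res$n_nuclei)
  expect_identical(res$neuro_mask, res$th_mask | res$tuj1_mask)
  # determinism
  res2 <- segment_scene(sc$field)
  expect_identical(res$cells, res2$cells)
})

test_that("raising the nuclei threshold never increases the nucleus count", {
  sc <- gen_neuro_scene(128, 128, n_cells = 15, seed = 6)
  counts <- vapply(c(50, 80, 120, 200), function(thr)
    segment_nuclei(sc$field$pixels[, , 1],
                   pipeline_thresholds(nuc_dog = thr))$n_nuclei, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("watershed splitting agrees with EBImage's object detection on counts", {
  sc <- gen_neuro_scene(128, 128, n_cells = 12, seed = 13)
  seg <- segment_nuclei(sc$field$pixels[, , 1])
  dm <- EBImage::distmap(EBImage::Image(matrix(as.numeric(seg$nuc_mask),
                                               128, 128)))
  ref <- max(EBImage::watershed(dm, tolerance = 1, ext = 1))
  expect_equal(seg$n_nuclei, ref)
})
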