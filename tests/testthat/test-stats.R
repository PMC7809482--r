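test_that("Mann-Whitney exact branch matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  r2 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 2 / 6)
  # exhaustive agreement with the enumeration oracle on random tie-free data
  set.seed(31)
  for (i in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    x <- sample(1000, na + nb)      # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    got <- mann_whitney_u(a, b)
    ora <- o_mw_enum(a, b)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p)
  }
})

test_that("Mann-Whitney approximation handles ties and identical groups", {
  a <- c(5, 5, 6, 7, 8)
  same <- mann_whitney_u(a, a)
  expect_equal(same$p, 1)
  expect_equal(same$method, "normal")
  # cross-check the tie-corrected approximation against wilcox.test
  set.seed(8)
  x <- sample(1:6, 20, replace = TRUE)
  y <- sample(3:9, 25, replace = TRUE)
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$p, ref$p.value)
  expect_equal(min(ref$statistic, length(x) * length(y) - ref$statistic),
               got$U, ignore_attr = TRUE)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis matches the hand rank-sum formula", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  r <- kruskal_wallis(g)
  expect_equal(r$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)  # 3.857...
  expect_equal(r$H, o_kw_hand(g))
  expect_equal(r$df, 1)
  g3 <- list(x = c(2, 9, 4), y = c(7, 1, 3, 8), z = c(6, 6, 5))
  expect_equal(kruskal_wallis(g3)$H, o_kw_hand(g3))
  ident <- kruskal_wallis(list(a = c(3, 3), b = c(3, 3), c = c(3, 3)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30, 0.4)   # continuous: tie-free
    H <- kruskal_wallis(list(a = a, b = b))$H
    z <- mann_whitney_u(a, b, correct = FALSE)$z
    expect_equal(H, z^2, tolerance = 1e-12)
  }
})

test_that("Dunn post-hoc matches the z formula, is antisymmetric and conservative", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  d <- dunn_posthoc(g, adjustment = "none")
  pair13 <- d[d$group_i == "a" & d$group_j == "c", ]
  expect_equal(pair13$z, -6 / sqrt((9 * 10 / 12) * (2 / 3)))  # -6/sqrt(5)
  db <- dunn_posthoc(g, adjustment = "bonferroni")
  expect_true(all(db$p_adjusted >= d$p_raw))
  expect_true(all(db$p_adjusted <= 1))
  # identical pair among three groups: z = 0, adjusted p = 1
  g2 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(10, 11, 12))
  d2 <- dunn_posthoc(g2)
  expect_equal(d2$z[d2$group_i == "a" & d2$group_j == "b"], 0)
  expect_equal(d2$p_adjusted[d2$group_i == "a" & d2$group_j == "b"], 1)
  # antisymmetry: listing the groups in the opposite order flips the sign
  zab <- d$z[d$group_i == "a" & d$group_j == "b"]
  d3 <- dunn_posthoc(list(b = c(4, 5, 6), a = c(1, 2, 3), c = c(7, 8, 9)),
                     adjustment = "none")
  expect_equal(d3$z[d3$group_i == "b" & d3$group_j == "a"], -zab)
})

test_that("capacity arithmetic floors partial plates and is monotone", {
  expect_equal(assay_capacity(1, 7680000, 384, 20000)$n_assay_plates, 1)
  expect_equal(assay_capacity(0, 1e7, 384, 20000)$n_assay_plates, 0)
  expect_equal(assay_capacity(10, 1.67e7, 384, 20000)$n_assay_plates, 21)
  base <- assay_capacity(10, 1.18e7, 384, 20000)$n_assay_plates
  expect_gte(assay_capacity(11, 1.18e7, 384, 20000)$n_assay_plates, base)
  expect_gte(assay_capacity(10, 1.3e7, 384, 20000)$n_assay_plates, base)
  expect_error(assay_capacity(-1, 1e7, 384, 20000), "non-negative")
  expect_error(assay_capacity(10, 0, 384, 20000), "positive")
})

test_that("seeding arithmetic converts concentration and volume", {
  expect_equal(seeding_cells_per_well(30000, 100), 3000)
  expect_equal(seeding_cells_per_well(1e6, 0), 0)
  expect_equal(seeding_cells_per_well(1000, 1), 1)
  expect_error(seeding_cells_per_well(-5, 10), "non-negative")
})
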