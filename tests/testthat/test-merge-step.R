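test_that("subregion density uses the convex hull area", {
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  d <- subregion_density(sq, weights = rep(25, 4))
  expect_equal(d$total_demand, 100)
  expect_equal(d$area, 1)
  expect_equal(d$density, 100)

  # doubling weights doubles density, area unchanged
  d2 <- subregion_density(sq, weights = rep(50, 4))
  expect_equal(d2$area, 1)
  expect_equal(d2$density, 200)

  # collinear members: zero hull area, degenerate density
  line <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0))
  dl <- subregion_density(line, weights = c(1, 1, 1))
  expect_equal(dl$area, 0)
  expect_true(is.na(dl$density))
})

test_that("quadrat test reproduces the hand-computed binomial expectation", {
  # 4 points, one per cell of a 2x2 grid
  co <- data.frame(x = c(0.25, 0.75, 0.25, 0.75), y = c(0.25, 0.25, 0.75, 0.75))
  h <- heterogeneity_test(co, n_cells = 4, alpha = 0.05,
                          extent = c(0, 1, 0, 1))
  expect_equal(h$n_cells, 4L)
  expect_equal(h$p_cell, 0.25)
  # E(i) = 4 * C(4,i) 0.25^i 0.75^(4-i), computed by hand
  expect_equal(h$expected, c(1.26563, 1.6875, 0.84375, 0.1875, 0.01563),
               tolerance = 1e-4)
  expect_equal(h$observed, c(0L, 4L, 0L, 0L, 0L))
  expect_equal(h$chi2, 5.4815, tolerance = 1e-3)
  expect_equal(h$dof, 4L)
  expect_false(h$reject) # homogeneous at alpha = 0.05
  expect_equal(sum(h$expected), h$n_cells, tolerance = 1e-6)
})

test_that("a fully concentrated subregion is flagged heterogeneous", {
  co <- data.frame(x = rep(0.01, 50), y = rep(0.01, 50))
  h <- heterogeneity_test(co, n_cells = 100, extent = c(0, 1, 0, 1))
  expect_true(h$reject)
  expect_gt(h$chi2, stats::qchisq(0.999, df = 50))
})

test_that("occupancy counts always cover every cell", {
  for (s in 1:5) {
    set.seed(s)
    co <- data.frame(x = stats::runif(30), y = stats::runif(30))
    h <- heterogeneity_test(co, n_cells = 25)
    expect_equal(sum(h$observed), h$n_cells)
    expect_equal(sum(h$expected), h$n_cells, tolerance = 1e-6)
    expect_gte(h$chi2, 0)
  }
})

test_that("classification separates a dense blob from a sparse field", {
  set.seed(31)
  blob <- data.frame(x = stats::runif(30), y = stats::runif(30))          # in [0,1]^2
  field <- data.frame(x = stats::runif(30, 0, 100), y = stats::runif(30, 0, 100))
  pts <- data.frame(id = sprintf("p%02d", 1:60),
                    x = c(blob$x, field$x), y = c(blob$y, field$y),
                    weight = c(rep(10, 30), rep(1, 30)))
  inst <- pmedian_instance(pts, p = 5)
  labels <- rep(1:2, each = 30)
  cl <- classify_subregions(inst, labels)
  expect_true(cl$is_clustered[1])  # dense AND concentrated
  expect_false(cl$is_clustered[2]) # spread like the region itself
  expect_false(cl$is_sparse[1])
  # single-member subregions are degenerate, hence sparse
  cl2 <- classify_subregions(inst, c(1L, rep(2L, 59)))
  expect_true(cl2$is_sparse[1])
})

test_that("a subregion exactly at region density is not sparse", {
  # one subregion covering everything: density equals region density
  inst <- random_instance(40, 4, seed = 8)
  cl <- classify_subregions(inst, rep(1L, 40))
  expect_false(cl$is_sparse[1])
})

test_that("merge dissolves non-clustered subregions by nearest centroid", {
  # two dense blobs at x = 0 and x = 100, sparse strip between them
  set.seed(13)
  mk <- function(cx, n, s, w) data.frame(x = cx + stats::rnorm(n, sd = s),
                                         y = stats::rnorm(n, sd = s),
                                         weight = w)
  a <- mk(0, 25, 0.5, 20); b <- mk(100, 25, 0.5, 20)
  strip <- data.frame(x = stats::runif(20, 10, 90),
                      y = stats::runif(20, -20, 20), weight = 1)
  pts <- rbind(a, b, strip)
  pts <- data.frame(id = sprintf("m%02d", seq_len(nrow(pts))), pts)
  inst <- pmedian_instance(pts, p = 6)
  labels <- rep(1:3, times = c(25, 25, 20))
  cl <- classify_subregions(inst, labels)
  expect_true(all(cl$is_clustered[1:2]))
  expect_false(cl$is_clustered[3])
  mg <- merge_nonclustered(inst, labels, cl)
  expect_equal(mg$q, 2L)
  # partition: every point labelled, demand conserved
  expect_true(all(mg$labels %in% 1:2))
  expect_equal(length(mg$labels), nrow(pts))
  for (qq in 1:2)
    expect_gt(sum(inst$points$weight[mg$labels == qq]), 0)
  expect_equal(sum(inst$points$weight[mg$labels == 1]) +
               sum(inst$points$weight[mg$labels == 2]),
               sum(pts$weight))
  # strip points split by nearest pre-merge centroid (about x = 50)
  strip_idx <- 51:70
  expect_identical(mg$labels[strip_idx] == 1L, pts$x[strip_idx] < 50)
  # with every subregion clustered the merge is a no-op (q = k)
  inst2 <- pmedian_instance(pts[1:50, ], p = 6)
  cl2 <- classify_subregions(inst2, labels[1:50])
  mg2 <- merge_nonclustered(inst2, labels[1:50], cl2)
  expect_equal(mg2$q, sum(cl2$is_clustered))
  expect_identical(mg2$labels, labels[1:50])
})

test_that("a region with no clustered subregion raises the fallback signal", {
  inst <- random_instance(60, 5, seed = 2) # uniform scatter everywhere
  labels <- rep(1:2, each = 30)
  cl <- classify_subregions(inst, labels)
  expect_false(any(cl$is_clustered))
  expect_error(merge_nonclustered(inst, labels, cl),
               class = "emfi_fully_homogeneous")
})
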