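test_that("Davies-Bouldin index matches hand computations", {
  # two singleton clusters: zero scatter, index 0
  x <- rbind(c(0, 0), c(10, 0))
  expect_equal(davies_bouldin_index(x, c(1, 2)), 0)

  # {(0,0),(0,2)} and {(10,0),(10,2)}: S = 1 each, centroid gap 10 -> 0.2
  x2 <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  expect_equal(davies_bouldin_index(x2, c(1, 1, 2, 2)), 0.2)

  expect_error(davies_bouldin_index(x2, rep(1, 4)), "at least 2 clusters")
  expect_error(davies_bouldin_index(rbind(c(0, 0), c(0, 2), c(0, 1), c(0, 1)),
                                    c(1, 1, 2, 2)), "degenerate")
})

test_that("index agrees with an independent naive implementation", {
  set.seed(55)
  x <- matrix(stats::runif(100, 0, 50), ncol = 2)
  for (r in 1:100) {
    k <- sample(2:5, 1)
    lab <- sample(seq_len(k), 50, replace = TRUE)
    if (length(unique(lab)) < 2) next
    got <- tryCatch(davies_bouldin_index(x, lab), error = function(e) NULL)
    if (is.null(got)) next
    expect_equal(got, naive_db_index(x, lab), tolerance = 1e-9)
  }
})

test_that("partition-count selection recovers separated facility blobs", {
  set.seed(23)
  centers <- rbind(c(0, 0), c(100, 0), c(50, 90))
  fac <- centers[rep(1:3, each = 8), ] + matrix(stats::rnorm(48, sd = 2),
                                                ncol = 2)
  expect_equal(select_partition_count(fac, k_max = 8, seed = 3), 3L)
  expect_equal(select_partition_count(fac, k_max = 2, seed = 3), 2L)
  expect_error(select_partition_count(fac, k_max = 1), "invalid k_max")
})

test_that("facility partitions carry warm starts and their service areas", {
  inst <- blob_instance(n_blobs = 2, per_blob = 15, separation = 150,
                        spread = 1, seed = 9, p = 6)
  d <- pairwise_distances(inst)
  sol <- fast_interchange(inst, random_initial_solution(inst, 1), dmat = d)
  fp <- build_facility_subproblems(inst, sol, k = 2, seed = 5)
  expect_equal(fp$k, 2L)
  all_fac <- sort(unlist(lapply(fp$parts, `[[`, "facilities")))
  all_dst <- sort(unlist(lapply(fp$parts, `[[`, "destinations")))
  expect_identical(all_fac, sol$facilities)          # facilities partitioned
  expect_identical(all_dst, seq_len(30))             # destinations partitioned
  expect_equal(sum(vapply(fp$parts, `[[`, integer(1), "p_part")), 6L)
  # two separated facility blobs split along the blobs
  for (part in fp$parts)
    expect_equal(length(unique(inst$labels[part$facilities])), 1L)
  # k = p: every part is one facility with its service area
  fp2 <- build_facility_subproblems(inst, sol, k = 6, seed = 5)
  expect_true(all(vapply(fp2$parts, `[[`, integer(1), "p_part") == 1L))
  for (part in fp2$parts)
    expect_setequal(part$destinations, which(sol$assignment == part$facilities))
})

test_that("distance decomposition descends and stalls at local optima", {
  inst <- random_instance(40, 8, seed = 31)
  d <- pairwise_distances(inst)
  warm <- fast_interchange(inst, random_initial_solution(inst, 2), dmat = d)
  cfg <- emfi_config(seed = 7)
  res <- iterate_distance_decomposition(inst, warm, cfg, dmat = d)
  expect_true(all(diff(res$trace$z) <= 1e-9))
  expect_lte(res$solution$objective, warm$objective)
  # a globally FI-optimal warm start terminates with unchanged cost
  res2 <- iterate_distance_decomposition(inst, res$solution, cfg, dmat = d)
  expect_equal(res2$solution$objective, res$solution$objective)
})

test_that("distance decomposition reaches the oracle optimum on small fixtures", {
  inst <- random_instance(12, 3, seed = 61)
  d <- pairwise_distances(inst)
  opt <- brute_force_optimum(inst, dmat = d)$objective
  warm <- evaluate_solution(inst, c(1, 2, 3), dmat = d)
  res <- iterate_distance_decomposition(inst, warm, emfi_config(seed = 5),
                                        dmat = d)
  expect_equal(res$solution$objective, opt)
})
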