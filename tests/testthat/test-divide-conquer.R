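test_that("facility apportionment follows floors plus demand-ordered round robin", {
  # floors [4,2,0], 1 leftover -> largest demand first
  expect_equal(apportion_facilities(c(600, 300, 100), 7), c(5L, 2L, 0L))
  expect_equal(apportion_facilities(1234, 9), 9L)
  # demand tie on the leftover: lower index wins
  expect_equal(apportion_facilities(c(100, 100), 5), c(3L, 2L))
  # capacity overflow redistributes down the demand order
  expect_equal(apportion_facilities(c(1000, 10), 6, capacities = c(2, 5)),
               c(2L, 4L))
  expect_error(apportion_facilities(c(10, 10), 7, capacities = c(3, 3)),
               "infeasible cardinality")
})

test_that("apportionment conserves the facility count on random inputs", {
  set.seed(99)
  for (r in 1:1000) {
    q <- sample(1:12, 1)
    demands <- stats::runif(q, 1, 1000)
    p <- sample(1:50, 1)
    caps <- sample(5:60, q, replace = TRUE)
    if (p > sum(caps)) next
    ps <- apportion_facilities(demands, p, capacities = caps)
    expect_identical(sum(ps), p)
    expect_true(all(ps >= 0L & ps <= caps))
  }
})

test_that("subsolver choice respects the scale thresholds", {
  cfg <- emfi_config(milp_max_n = 300, milp_max_p = 30)
  expect_equal(choose_subsolver(100, 10, cfg), "MILP")
  expect_equal(choose_subsolver(301, 10, cfg), "FI")
  expect_equal(choose_subsolver(100, 31, cfg), "FI")
  expect_equal(choose_subsolver(100, 0, cfg), "none")
})

test_that("subproblems are solved independently on their own members", {
  inst <- blob_instance(n_blobs = 2, per_blob = 12, separation = 200,
                        spread = 1, seed = 4, p = 2)
  labels <- inst$labels
  cfg <- emfi_config(seed = 5)
  sets <- solve_subproblems(inst, labels, c(1L, 1L), cfg)
  # each subproblem returns its blob's exact 1-median
  for (b in 1:2) {
    m <- which(labels == b)
    sub <- pmedian_instance(inst$points[m, ], p = 1)
    expect_identical(sets[[b]], m[brute_force_optimum(sub)$facilities])
  }
  # small subproblems route through the exact solver and match brute force
  expect_equal(choose_subsolver(12, 1, cfg), "MILP")
})

test_that("results are invariant to the worker count", {
  inst <- blob_instance(n_blobs = 4, per_blob = 20, separation = 80,
                        spread = 2, seed = 14, p = 12)
  r1 <- run_em_fi(inst, emfi_config(seed = 6, workers = 1L))
  r4 <- run_em_fi(inst, emfi_config(seed = 6, workers = 4L))
  expect_identical(r1$solution$facilities, r4$solution$facilities)
  expect_identical(r1$solution$objective, r4$solution$objective)
  expect_identical(r1$report$q, r4$report$q)
})

test_that("conquer reassignment can only improve on the subproblem sum", {
  inst <- blob_instance(n_blobs = 3, per_blob = 10, separation = 90,
                        spread = 1.5, seed = 21, p = 6)
  labels <- inst$labels
  demands <- vapply(1:3, function(b) sum(inst$points$weight[labels == b]),
                    numeric(1))
  p_subs <- apportion_facilities(demands, 6, capacities = tabulate(labels))
  cfg <- emfi_config(seed = 2)
  sets <- solve_subproblems(inst, labels, p_subs, cfg)
  sub_z <- sum(vapply(1:3, function(b) {
    m <- which(labels == b)
    sub <- pmedian_instance(inst$points[m, ], p = p_subs[b])
    evaluate_solution(sub, match(sets[[b]], m))$objective
  }, numeric(1)))
  sol <- conquer_reassign(inst, sets)
  expect_lte(sol$objective, sub_z + 1e-9)
  expect_equal(length(sol$facilities), 6L)
  # union of the wrong size is an internal invariant breach
  expect_error(conquer_reassign(inst, sets[1:2]), "apportionment breach")
})

test_that("global improvement never worsens the reassignment solution", {
  inst <- random_instance(30, 5, seed = 77)
  d <- pairwise_distances(inst)
  warm <- evaluate_solution(inst, c(2, 8, 15, 22, 29), dmat = d)
  cfg <- emfi_config(seed = 1)
  imp <- improve_global(inst, warm, cfg, dmat = d)
  expect_lte(imp$objective, warm$objective)
  # a locally optimal warm start is a fixed point
  again <- improve_global(inst, imp, cfg, dmat = d)
  expect_identical(again$facilities, imp$facilities)
})

test_that("the full pipeline is deterministic and decomposes blob fixtures", {
  inst <- blob_instance(n_blobs = 4, per_blob = 20, separation = 80,
                        spread = 2, seed = 3, p = 12)
  cfg <- emfi_config(seed = 9)
  r1 <- run_em_fi(inst, cfg)
  r2 <- run_em_fi(inst, cfg)
  expect_identical(r1$solution$facilities, r2$solution$facilities)
  expect_gte(r1$report$q, 2)
  expect_equal(length(r1$solution$facilities), 12L)
  # improvement is never worse than reassignment
  ri <- run_em_fi(inst, emfi_config(seed = 9, improve_mode = "global_fi"))
  expect_lte(ri$solution$objective, ri$reassignment$objective)
})

test_that("separated blobs with p = #blobs reach the exact optimum", {
  inst <- blob_instance(n_blobs = 3, per_blob = 9, separation = 120,
                        spread = 1, seed = 8, p = 3)
  opt <- brute_force_optimum(inst)
  r <- run_em_fi(inst, emfi_config(seed = 4, improve_mode = "global_fi"))
  expect_equal(r$solution$objective, opt$objective)
})

test_that("homogeneous instances fall back but still return a valid solution", {
  inst <- random_instance(60, 15, seed = 19)
  r <- run_em_fi(inst, emfi_config(seed = 2))
  expect_equal(r$report$fallback, "global_fi")
  expect_equal(length(r$solution$facilities), 15L)
  rd <- run_em_fi(inst, emfi_config(seed = 2,
                                    improve_mode = "distance_decomposition"))
  expect_equal(rd$report$fallback, "distance_decomposition")
  expect_equal(length(rd$solution$facilities), 15L)
  expect_lte(rd$solution$objective, rd$reassignment$objective + 1e-9)
})
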