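two_blob_coords <- function(n = 400, sep = 100, spread = 1, seed = 2,
                            share = 0.5) {
  set.seed(seed)
  lab <- 1L + (stats::runif(n) > share)
  mu <- rbind(c(0, 0), c(sep, sep))
  list(x = mu[lab, ] + matrix(stats::rnorm(2 * n, sd = spread), ncol = 2),
       lab = lab)
}

test_that("single-component fit is the closed-form Gaussian MLE", {
  set.seed(4)
  x <- matrix(stats::rnorm(200, sd = 3), ncol = 2)
  m <- fit_gmm(x, c = 1)
  expect_equal(m$weights, 1)
  expect_equal(m$means[1, ], colMeans(x))
  expect_equal(m$covariances[[1]], stats::cov(x) * 99 / 100,
               tolerance = 1e-4) # MLE covariance, up to the tiny ridge
  expect_equal(m$parameter_count, 5L)
})

test_that("BIC follows ln(n) c_m - 2 logLik with c_m = 6c - 1", {
  expect_equal(bic_score(-12.5, 1, 3), 25) # ln(1) = 0
  # two components: 1 free weight + 4 means + 6 covariance entries = 11
  expect_equal(bic_score(-100, 100, 2), log(100) * 11 + 200)
  expect_equal(bic_score(-100, 100, 2), 250.6517, tolerance = 1e-4)
  expect_error(bic_score(-1, 0, 2), "invalid n")
})

test_that("model bic field always equals bic_score of its own fit", {
  tb <- two_blob_coords()
  for (c in 1:3) {
    m <- fit_gmm(tb$x, c, seed = 5)
    expect_equal(m$bic, bic_score(m$log_likelihood, nrow(tb$x), c))
  }
})

test_that("EM recovers two well-separated blobs", {
  tb <- two_blob_coords(n = 400)
  m <- fit_gmm(tb$x, 2, seed = 1)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  # match components to blobs by nearest mean
  perm <- if (sum((m$means[1, ] - c(0, 0))^2) <
              sum((m$means[2, ] - c(0, 0))^2)) 1:2 else 2:1
  for (b in 1:2) {
    blob_mean <- colMeans(tb$x[tb$lab == b, , drop = FALSE])
    expect_lt(sqrt(sum((m$means[perm[b], ] - blob_mean)^2)), 0.5)
  }
  # EM ascent: the tracked log-likelihood never decreases
  expect_true(all(diff(m$loglik_trace) >= -1e-6 * abs(m$log_likelihood)))
})

test_that("degenerate mixtures are refused", {
  x <- matrix(c(0, 0, 0, 0, 1, 1), ncol = 2, byrow = TRUE)
  expect_error(fit_gmm(x, 3), "degenerate mixture")
  expect_error(fit_gmm(x[1, , drop = FALSE], 2), "degenerate mixture")
})

test_that("labels are maximum-posterior and responsibilities normalised", {
  tb <- two_blob_coords(n = 300)
  m <- fit_gmm(tb$x, 2, seed = 3)
  lb <- label_points(m, tb$x)
  expect_equal(rowSums(lb$responsibilities), rep(1, 300), tolerance = 1e-9)
  expect_identical(lb$label, apply(lb$responsibilities, 1, which.max))
  # a point exactly at a component mean belongs to it under equal weights
  sym <- new_env_model <- fit_gmm(rbind(matrix(stats::rnorm(100), ncol = 2),
                                        matrix(stats::rnorm(100) + 50, ncol = 2)),
                                  2, seed = 1)
  at_mu1 <- label_points(sym, matrix(sym$means[1, ], 1))
  expect_equal(at_mu1$label, 1L)
  # generative truth recovered at separation 10
  agree <- max(mean(lb$label == tb$lab), mean(lb$label == 3 - tb$lab))
  expect_gte(agree, 0.99)
})

test_that("BIC sweep selects the generative component count and is seeded", {
  inst <- blob_instance(n_blobs = 4, per_blob = 40, separation = 60,
                        spread = 2, seed = 6)
  sel <- select_component_model(inst, c_max = 8, seed = 2)
  expect_equal(sel$k, 4L)
  expect_equal(sel$model$bic, min(sel$bic_table$bic))
  expect_equal(sel$bic_table$c[which.min(sel$bic_table$bic)], 4L)
  sel2 <- select_component_model(inst, c_max = 8, seed = 2)
  expect_identical(sel$bic_table, sel2$bic_table)
  expect_identical(sel$labeling$label, sel2$labeling$label)
  # c_max = 2 sweeps a single candidate
  sel3 <- select_component_model(inst, c_max = 2, seed = 2)
  expect_equal(sel3$k, 2L)
  expect_equal(nrow(sel3$bic_table), 1L)
})

test_that("mixture log-likelihood agrees with an independent EM (mclust)", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC # Mclust() resolves this in the caller frame
  tb <- two_blob_coords(n = 500, seed = 12)
  m <- fit_gmm(tb$x, 2, seed = 4)
  mc <- mclust::Mclust(tb$x, G = 2, modelNames = "VVV", verbose = FALSE)
  # same maximum under two independent implementations
  expect_equal(m$log_likelihood, mc$loglik, tolerance = 1e-3)
  # mclust reports BIC as 2 logLik - ln(n) df: same df, opposite sign
  expect_equal(m$bic, -as.numeric(mc$BIC), tolerance = 1e-2)
})
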