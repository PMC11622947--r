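# Bivariate Gaussian mixture fitting by EM, model selection by BIC.
# Coordinates only are modelled (demand weights enter the pipeline later,
# through density classification and facility apportionment).

# log density of each row of x under N(mu, sigma), 2-D, in log space
log_dmvnorm2 <- function(x, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; cc <- sigma[2, 2]
  det <- a * cc - b * b
  if (!is.finite(det) || det <= 0) return(rep(-Inf, nrow(x)))
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (cc * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

ridge_pd <- function(sigma) {
  eps <- 1e-6 * (sigma[1, 1] + sigma[2, 2])
  if (!is.finite(eps) || eps <= 0) eps <- 1e-10
  for (k in 0:12) {
    s <- sigma + diag(eps * 10^k, 2)
    if (s[1, 1] * s[2, 2] - s[1, 2]^2 > 0 && s[1, 1] > 0) return(s)
  }
  diag(max(eps, 1e-8), 2)
}

# k-means++ seeding over the (distinct) coordinates; uses the current RNG
kmeanspp_centers <- function(x, c) {
  ux <- unique(x)
  if (nrow(ux) < c) stop("degenerate mixture: fewer distinct points than components")
  centers <- matrix(NA_real_, c, 2)
  centers[1, ] <- ux[sample.int(nrow(ux), 1L), ]
  d2 <- (ux[, 1] - centers[1, 1])^2 + (ux[, 2] - centers[1, 2])^2
  for (k in seq_len(c - 1L) + 1L) {
    pick <- if (all(d2 == 0)) sample.int(nrow(ux), 1L) else
      sample.int(nrow(ux), 1L, prob = d2)
    centers[k, ] <- ux[pick, ]
    d2 <- pmin(d2, (ux[, 1] - centers[k, 1])^2 + (ux[, 2] - centers[k, 2])^2)
  }
  centers
}

em_single_run <- function(x, c, tol, max_iter) {
  n <- nrow(x)
  centers <- kmeanspp_centers(x, c)
  # hard-assign to nearest seeded center for the starting responsibilities
  d2 <- vapply(seq_len(c), function(k)
    (x[, 1] - centers[k, 1])^2 + (x[, 2] - centers[k, 2])^2, numeric(n))
  hard <- max.col(-d2, ties.method = "first")
  resp <- matrix(0, n, c)
  resp[cbind(seq_len(n), hard)] <- 1
  glob <- ridge_pd(stats::cov(x) * (n - 1) / max(n, 2))

  m_step <- function(resp) {
    nk <- pmax(colSums(resp), 1e-12)
    theta <- nk / n
    means <- crossprod(resp, x) / nk
    covs <- vector("list", c)
    for (k in seq_len(c)) {
      dx <- x[, 1] - means[k, 1]; dy <- x[, 2] - means[k, 2]
      r <- resp[, k]
      s <- matrix(c(sum(r * dx * dx), sum(r * dx * dy),
                    sum(r * dx * dy), sum(r * dy * dy)) / nk[k], 2)
      if (nk[k] < 2 || !is.finite(sum(s))) s <- glob
      covs[[k]] <- ridge_pd(s)
    }
    list(theta = theta, means = means, covs = covs)
  }

  par <- m_step(resp)
  ll_trace <- numeric(0)
  ll <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- vapply(seq_len(c), function(k)
      log(par$theta[k]) + log_dmvnorm2(x, par$means[k, ], par$covs[[k]]),
      numeric(n))
    mx <- apply(lw, 1, max)
    ll_i <- mx + log(rowSums(exp(lw - mx)))
    new_ll <- sum(ll_i)
    resp <- exp(lw - ll_i)
    ll_trace <- c(ll_trace, new_ll)
    if (is.finite(ll) && abs(new_ll - ll) < tol * abs(new_ll)) { ll <- new_ll; break }
    ll <- new_ll
    par <- m_step(resp)
  }
  list(par = par, loglik = ll, resp = resp, trace = ll_trace)
}

#' Fit a c-component bivariate Gaussian mixture by EM
#'
#' Runs expectation-maximisation from `n_init` k-means++-seeded starts and
#' keeps the restart with the highest converged log-likelihood. Covariances
#' are full (unconstrained) with a small trace-proportional ridge guarding
#' against singularity; the free-parameter count is therefore `6c - 1`
#' (`c - 1` weights, `2c` means, `3c` covariance entries). For `c = 1` the
#' maximum-likelihood fit is closed-form (coordinate mean and MLE covariance).
#'
#' @param points a `pmedian_instance` or a two-column coordinate matrix /
#'   data.frame with `x`, `y`.
#' @param c number of mixture components, `1 <= c <=` number of distinct
#'   coordinates.
#' @param seed integer seed for the restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param n_init number of seeded restarts.
#' @return a `gmm_model`: list with `c`, `weights`, `means` (c x 2),
#'   `covariances` (list of 2 x 2), `log_likelihood`, `loglik_trace` (best
#'   restart), `parameter_count`, `bic` and `n`.
#' @export
fit_gmm <- function(points, c, seed = 1L, tol = 1e-4, max_iter = 200L,
                    n_init = 5L) {
  x <- coords_of(points)
  n <- nrow(x)
  c <- as.integer(c)
  if (c < 1L || n < c) stop("degenerate mixture: need n >= c >= 1")
  if (nrow(unique(x)) < c)
    stop("degenerate mixture: fewer distinct points than components")
  if (c == 1L) {
    mu <- colMeans(x)
    sig <- if (n == 1L) diag(1e-8, 2) else ridge_pd(stats::cov(x) * (n - 1) / n)
    ll <- sum(log_dmvnorm2(x, mu, sig))
    return(new_gmm(1L, 1, matrix(mu, 1), list(sig), ll, ll, n,
                   matrix(1, n, 1)))
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(as.integer(seed) + r - 1L)
    run <- tryCatch(em_single_run(x, c, tol, max_iter), error = function(e) NULL)
    if (!is.null(run) && is.finite(run$loglik) &&
        (is.null(best) || run$loglik > best$loglik)) best <- run
  }
  if (is.null(best)) stop("degenerate mixture: EM failed for c = ", c)
  new_gmm(c, best$par$theta, best$par$means, best$par$covs, best$loglik,
          best$trace, n, best$resp)
}

new_gmm <- function(c, theta, means, covs, ll, trace, n, resp) {
  structure(list(c = c, weights = as.numeric(theta),
                 means = unname(as.matrix(means)), covariances = covs,
                 log_likelihood = ll, loglik_trace = as.numeric(trace),
                 parameter_count = 6L * c - 1L,
                 bic = bic_score(ll, n, c), n = n,
                 responsibilities = unname(as.matrix(resp))),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("GMM: %d components, n = %d, logLik = %.4f, BIC = %.4f\n",
              x$c, x$n, x$log_likelihood, x$bic))
  invisible(x)
}

#' Bayesian information criterion for a fitted mixture
#'
#' `BIC = ln(n) * (6c - 1) - 2 * logLik`; lower is better. The parameter
#' count `6c - 1` is that of a full-covariance bivariate mixture.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param n number of data points.
#' @param c number of mixture components.
#' @return the BIC value.
#' @export
bic_score <- function(log_likelihood, n, c) {
  if (!is.numeric(n) || n < 1) stop("invalid n")
  log(n) * (6 * c - 1) - 2 * log_likelihood
}

#' Select the mixture order by BIC and label the points
#'
#' Fits mixtures for `c = 2 .. c_max` and returns the minimum-BIC model (ties
#' to the smaller `c`), its maximum-posterior point labelling and the selected
#' component count `k`. `c = 1` is never a candidate: the sweep exists to
#' decompose, and BIC ordering is relied on only within the swept range.
#'
#' @param points coordinates as in [fit_gmm()].
#' @param c_max largest component count to try (default 20; BIC ordering
#'   degrades for large `c`, so the cap should stay moderate).
#' @param seed integer seed.
#' @param ... passed to [fit_gmm()] (`tol`, `max_iter`, `n_init`).
#' @return list with `model` (`gmm_model`), `labeling` (from
#'   [label_points()]), `k` and `bic_table` (data.frame of `c`, `bic`,
#'   `log_likelihood`).
#' @export
select_component_model <- function(points, c_max = 20L, seed = 1L, ...) {
  x <- coords_of(points)
  if (nrow(x) < 2L) stop("need at least two points to decompose")
  c_max <- max(2L, as.integer(c_max))
  fits <- list()
  for (c in 2:c_max) {
    fit <- tryCatch(fit_gmm(x, c, seed = as.integer(seed) + 1000L * c, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) fits[[as.character(c)]] <- fit
  }
  if (length(fits) == 0L) stop("decomposition failed: no mixture order could be fitted")
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.min(bics)]]
  tab <- data.frame(c = as.integer(names(fits)), bic = unname(bics),
                    log_likelihood = vapply(fits, function(f) f$log_likelihood,
                                            numeric(1)))
  rownames(tab) <- NULL
  list(model = best, labeling = label_points(best, x), k = best$c,
       bic_table = tab)
}

#' Maximum-posterior component labels for points under a fitted mixture
#'
#' @param model a `gmm_model`.
#' @param points coordinates as in [fit_gmm()].
#' @return list with `label` (argmax responsibility per point) and
#'   `responsibilities` (n x c matrix, rows summing to one).
#' @export
label_points <- function(model, points) {
  stopifnot(inherits(model, "gmm_model"))
  x <- coords_of(points)
  n <- nrow(x)
  lw <- vapply(seq_len(model$c), function(k)
    log(model$weights[k]) + log_dmvnorm2(x, model$means[k, ],
                                         model$covariances[[k]]),
    numeric(n))
  lw <- matrix(lw, nrow = n)
  mx <- apply(lw, 1, max)
  resp <- exp(lw - (mx + log(rowSums(exp(lw - mx)))))
  list(label = max.col(resp, ties.method = "first"), responsibilities = resp)
}
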