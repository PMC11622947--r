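# Shared fixtures, built in code.

# 3-4-5 right-triangle instance: A(0,0,w=1), B(3,0,w=2), C(0,4,w=1).
# Known by hand: p=1 optimum {B} Z=8; p=2 optimum {B,C} Z=3; p=3 Z=0.
t3_instance <- function(p = 2) {
  pmedian_instance(
    data.frame(id = c("A", "B", "C"), x = c(0, 3, 0), y = c(0, 0, 4),
               weight = c(1, 2, 1)),
    p = p)
}

random_instance <- function(n, p, seed) {
  set.seed(seed)
  pmedian_instance(
    data.frame(id = sprintf("r%03d", seq_len(n)),
               x = stats::runif(n, 0, 100), y = stats::runif(n, 0, 100),
               weight = sample(1:20, n, replace = TRUE)),
    p = p)
}

# Well-separated Gaussian blobs on a ring; returns an instance with $labels.
blob_instance <- function(n_blobs = 4, per_blob = 10, separation = 100,
                          spread = 1, seed = 1, p = n_blobs,
                          weights = NULL) {
  set.seed(seed)
  ang <- 2 * pi * seq_len(n_blobs) / n_blobs
  centers <- cbind(separation * cos(ang), separation * sin(ang))
  lab <- rep(seq_len(n_blobs), each = per_blob)
  xy <- centers[lab, ] + matrix(stats::rnorm(2 * n_blobs * per_blob,
                                             sd = spread), ncol = 2)
  n <- nrow(xy)
  if (is.null(weights)) weights <- sample(1:10, n, replace = TRUE)
  inst <- pmedian_instance(
    data.frame(id = sprintf("b%03d", seq_len(n)), x = xy[, 1], y = xy[, 2],
               weight = weights),
    p = p)
  inst$labels <- lab
  inst$gen_centers <- centers
  inst
}

# naive O(p n) re-evaluation of a single swap, for cross-checking best_swap
naive_swap_delta <- function(instance, facilities, enter, leave, dmat) {
  z0 <- evaluate_solution(instance, facilities, dmat = dmat)$objective
  swapped <- sort(c(setdiff(facilities, leave), enter))
  evaluate_solution(instance, swapped, dmat = dmat)$objective - z0
}

# independent naive Davies-Bouldin implementation (plain loops)
naive_db_index <- function(coords, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  cen <- list(); S <- numeric(k)
  for (i in seq_len(k)) {
    m <- coords[labels == ids[i], , drop = FALSE]
    cen[[i]] <- c(mean(m[, 1]), mean(m[, 2]))
    S[i] <- mean(sqrt((m[, 1] - cen[[i]][1])^2 + (m[, 2] - cen[[i]][2])^2))
  }
  per_cluster <- numeric(k)
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      gap <- sqrt(sum((cen[[i]] - cen[[j]])^2))
      best <- max(best, (S[i] + S[j]) / gap)
    }
    per_cluster[i] <- best
  }
  mean(per_cluster)
}
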