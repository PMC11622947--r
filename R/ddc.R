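# Iterative distance-based decomposition: partition the *current facilities*
# by k-means (k picked by the Davies-Bouldin index), solve each part with
# warm-started fast interchange over the destinations it currently serves,
# union, reassign globally, then repeat with k-1 until the cost stalls or the
# k = 1 pass (a plain global warm-started fast interchange) has run.

#' Davies-Bouldin index of a clustering
#'
#' Scatter `S_i` is the mean Euclidean distance of a cluster's members to its
#' centroid; for each pair `R_ij = (S_i + S_j) / d(centroid_i, centroid_j)`;
#' the index is the mean over clusters of `max_j R_ij`. Lower is better.
#'
#' @param points coordinates (matrix or data.frame `x`, `y`).
#' @param labels cluster label per point; at least two non-empty clusters.
#' @return the index value (non-negative).
#' @export
davies_bouldin_index <- function(points, labels) {
  x <- coords_of(points)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) stop("need at least 2 clusters")
  cen <- t(vapply(ids, function(l)
    colMeans(x[labels == l, , drop = FALSE]), numeric(2)))
  S <- vapply(seq_len(k), function(i) {
    m <- x[labels == ids[i], , drop = FALSE]
    mean(sqrt((m[, 1] - cen[i, 1])^2 + (m[, 2] - cen[i, 2])^2))
  }, numeric(1))
  dd <- as.matrix(stats::dist(cen))
  if (any(dd[upper.tri(dd)] == 0)) stop("degenerate clustering: coincident centroids")
  R <- outer(S, S, "+") / dd
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

# seeded k-means with retries until no cluster is empty/degenerate
seeded_kmeans <- function(x, k, seed, nstart = 10L, retries = 5L) {
  for (r in 0:retries) {
    set.seed(as.integer(seed) + r)
    km <- tryCatch(suppressWarnings(
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50L)),
      error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) return(km)
  }
  stop("degenerate partition: k-means could not produce ", k,
       " non-empty clusters")
}

#' Select the number of facility parts by the Davies-Bouldin index
#'
#' Runs seeded multi-start k-means for `k = 2..k_max` and returns the `k`
#' minimising the index (ties to the smaller `k`). `k` values whose
#' clustering is degenerate (empty clusters, coincident centroids) are
#' skipped.
#'
#' @param coords coordinates of the objects to partition.
#' @param k_max largest k to try (>= 2).
#' @param seed integer seed.
#' @return the selected `k`.
#' @export
select_partition_count <- function(coords, k_max, seed = 1L) {
  x <- coords_of(coords)
  if (k_max < 2L) stop("invalid k_max")
  k_max <- min(as.integer(k_max), nrow(unique(x)))
  if (k_max < 2L) return(1L)
  idx <- rep(NA_real_, k_max)
  for (k in 2:k_max) {
    km <- tryCatch(seeded_kmeans(x, k, seed = as.integer(seed) + 100L * k),
                   error = function(e) NULL)
    if (is.null(km)) next
    idx[k] <- tryCatch(davies_bouldin_index(x, km$cluster),
                       error = function(e) NA_real_)
  }
  if (all(is.na(idx))) return(2L)
  which.min(idx)
}

#' Partition the current facilities into warm-started subproblems
#'
#' k-means on the facility coordinates; each part's destination set is the
#' union of destinations currently assigned to the part's facilities, and its
#' warm start is the part's facilities themselves.
#'
#' @param instance a `pmedian_instance`.
#' @param solution the current `pmedian_solution`.
#' @param k number of parts, `2 <= k <= p`.
#' @param seed integer seed for k-means.
#' @return a `facility_partition`: list with `k` and `parts`, each part a
#'   list of `facilities` (warm start), `destinations` and `p_part`. Parts
#'   partition both the facility set and the destination set.
#' @export
build_facility_subproblems <- function(instance, solution, k, seed = 1L) {
  fac <- solution$facilities
  stopifnot(k >= 1L, k <= length(fac))
  fx <- instance$points[fac, c("x", "y")]
  lab <- if (k == 1L) rep(1L, length(fac))
  else if (k == length(fac)) seq_along(fac) # one facility per part
  else seeded_kmeans(as.matrix(fx), k, seed = seed)$cluster
  parts <- lapply(seq_len(k), function(part) {
    f <- fac[lab == part]
    d <- which(solution$assignment %in% f)
    list(facilities = f, destinations = d, p_part = length(f))
  })
  structure(list(k = k, parts = parts), class = "facility_partition")
}

# one distance-decomposition sweep at a given k; returns the reassigned solution
ddc_iteration <- function(instance, solution, k, config, seed, dmat) {
  if (k <= 1L) return(improve_global(instance, solution, config, dmat = dmat))
  fp <- build_facility_subproblems(instance, solution, k, seed = seed)
  sets <- lapply(seq_along(fp$parts), function(i) {
    part <- fp$parts[[i]]
    pts <- instance$points[part$destinations, , drop = FALSE]
    sub <- pmedian_instance(pts, p = part$p_part)
    sub_d <- dmat[part$destinations, part$destinations, drop = FALSE]
    warm <- match(part$facilities, part$destinations)
    if (anyNA(warm)) { # coincident facility served by a twin in another part
      free <- setdiff(seq_len(nrow(pts)), warm[!is.na(warm)])
      warm[is.na(warm)] <- free[seq_len(sum(is.na(warm)))]
    }
    sol <- fast_interchange(sub, warm,
                            max_iterations = config$fi_max_iterations,
                            dmat = sub_d)
    sort(part$destinations[sol$facilities])
  })
  conquer_reassign(instance, sets, dmat = dmat)
}

#' Iterative distance-based decomposition from a warm solution
#'
#' Selects an initial `k` over the facility coordinates via
#' [select_partition_count()], then repeats: partition the current facilities
#' into `k` parts, solve each part with warm-started fast interchange over the
#' destinations it serves, union and reassign globally, decrement `k`. The
#' loop stops when the objective is unchanged (relative change below
#' `ddc_stall_tol`) across two consecutive iterations, or after the `k = 1`
#' pass, which is a plain global warm-started fast interchange. The objective
#' never increases across iterations.
#'
#' @param instance a `pmedian_instance`.
#' @param solution warm-start `pmedian_solution`.
#' @param config an [emfi_config()].
#' @param dmat optional precomputed distance matrix.
#' @return list with `solution` (final) and `trace` (data.frame of `k` and
#'   end-of-iteration objective `z`).
#' @export
iterate_distance_decomposition <- function(instance, solution,
                                           config = emfi_config(),
                                           dmat = NULL) {
  d <- instance_dmat(instance, dmat)
  p <- instance$p
  kmax <- if (!is.null(config$ddc_kmax)) config$ddc_kmax else
    min(20L, as.integer(ceiling(sqrt(p))))
  k <- if (p >= 2L && kmax >= 2L)
    select_partition_count(instance$points[solution$facilities, c("x", "y")],
                           k_max = min(kmax, p), seed = derive_seed(config$seed, 2L))
  else 1L
  trace <- data.frame(k = integer(0), z = numeric(0))
  z_prev <- solution$objective
  current <- solution
  while (k >= 1L) {
    current <- ddc_iteration(instance, current, k, config,
                             seed = derive_seed(config$seed, 100L + k), d)
    trace <- rbind(trace, data.frame(k = k, z = current$objective))
    if (abs(z_prev - current$objective) <=
        config$ddc_stall_tol * max(1, abs(z_prev))) break
    z_prev <- current$objective
    k <- k - 1L
  }
  list(solution = current, trace = trace)
}

# distance decomposition without a warm solution (fully homogeneous regions):
# the first iteration partitions the *destinations* by k-means with
# demand-proportional facility counts, then the standard iteration takes over.
ddc_from_scratch <- function(instance, config, dmat = NULL) {
  d <- instance_dmat(instance, dmat)
  n <- nrow(instance$points)
  p <- instance$p
  kmax <- if (!is.null(config$ddc_kmax)) config$ddc_kmax else
    min(20L, as.integer(ceiling(sqrt(p))))
  x <- as.matrix(instance$points[, c("x", "y")])
  k <- if (kmax >= 2L && p >= 2L)
    select_partition_count(x, k_max = min(kmax, p),
                           seed = derive_seed(config$seed, 3L))
  else 1L
  if (k <= 1L) {
    init <- random_initial_solution(instance, seed = derive_seed(config$seed, 1L))
    sol <- fast_interchange(instance, init,
                            max_iterations = config$fi_max_iterations, dmat = d)
    return(list(initial = sol, solution = sol,
                trace = data.frame(k = 1L, z = sol$objective)))
  }
  lab <- seeded_kmeans(x, k, seed = derive_seed(config$seed, 4L))$cluster
  members <- split(seq_len(n), lab)
  demands <- vapply(members, function(m) sum(instance$points$weight[m]),
                    numeric(1))
  p_subs <- apportion_facilities(demands, p, capacities = lengths(members))
  sets <- solve_subproblems(instance, lab, p_subs, config, dmat = d)
  initial <- conquer_reassign(instance, sets, dmat = d)
  res <- iterate_distance_decomposition(instance, initial, config, dmat = d)
  list(initial = initial, solution = res$solution, trace = res$trace)
}
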