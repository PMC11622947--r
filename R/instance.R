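#' Construct a p-median problem instance
#'
#' An instance bundles the demand points (destinations), the number of
#' facilities `p` to locate, and the candidate facility sites. Facilities are
#' co-located with demand points, so candidates are row indices into `points`;
#' by default every demand point is a candidate.
#'
#' @param points a data.frame with columns `id` (unique identifiers), `x`, `y`
#'   (planar coordinates; geographic inputs must be projected by the caller)
#'   and `weight` (non-negative demand).
#' @param p number of facilities to select, `1 <= p <= length(candidates)`.
#' @param candidates integer vector of row indices eligible as facility sites;
#'   defaults to all points.
#' @return an object of class `pmedian_instance` with elements `points`, `p`
#'   and `candidates`.
#' @examples
#' tri <- data.frame(id = c("A", "B", "C"), x = c(0, 3, 0), y = c(0, 0, 4),
#'                   weight = c(1, 2, 1))
#' inst <- pmedian_instance(tri, p = 2)
#' @export
pmedian_instance <- function(points, p, candidates = NULL) {
  points <- validate_points(points)
  n <- nrow(points)
  if (is.null(candidates)) candidates <- seq_len(n)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) < 1L || any(candidates < 1L) || any(candidates > n))
    stop("candidate indices must lie in 1..n")
  p <- as.integer(p)
  if (is.na(p) || p < 1L || p > length(candidates))
    stop("cardinality violation: need 1 <= p <= |candidates|")
  structure(list(points = points, p = p, candidates = candidates),
            class = "pmedian_instance")
}

validate_points <- function(points) {
  points <- as.data.frame(points)
  req <- c("id", "x", "y", "weight")
  if (!all(req %in% names(points)))
    stop("points must have columns id, x, y, weight")
  if (nrow(points) < 1L) stop("empty instance")
  if (anyDuplicated(points$id))
    stop("duplicate id: ", points$id[anyDuplicated(points$id)][1L])
  for (col in c("x", "y", "weight")) {
    v <- points[[col]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("column '", col, "' must be finite numeric")
  }
  if (any(points$weight < 0)) stop("negative demand weight")
  rownames(points) <- NULL
  points[, req]
}

#' @export
print.pmedian_instance <- function(x, ...) {
  cat(sprintf("p-median instance: n = %d destinations, p = %d, %d candidate sites\n",
              nrow(x$points), x$p, length(x$candidates)))
  cat(sprintf("total demand = %g\n", sum(x$points$weight)))
  invisible(x)
}

#' Pairwise Euclidean distances between demand points
#'
#' @param x a `pmedian_instance`, or a data.frame/matrix with `x`, `y` columns.
#' @return a symmetric n x n matrix of Euclidean distances with zero diagonal.
#' @export
pairwise_distances <- function(x) {
  co <- coords_of(x)
  if (nrow(co) < 1L) stop("empty instance")
  if (any(!is.finite(co))) stop("coordinates must be finite")
  m <- as.matrix(stats::dist(co))
  dimnames(m) <- NULL
  m
}

coords_of <- function(x) {
  if (inherits(x, "pmedian_instance")) x <- x$points
  if (is.matrix(x)) return(x[, 1:2, drop = FALSE])
  as.matrix(x[, c("x", "y")])
}

# distance matrix for an instance, memoised on the object environment-free way:
# callers inside one pipeline stage compute it once and pass it down.
instance_dmat <- function(instance, dmat = NULL) {
  if (is.null(dmat)) pairwise_distances(instance) else dmat
}

#' Evaluate a facility set on an instance
#'
#' Assigns every destination to its nearest facility in the set (distance ties
#' broken by the lowest facility index) and computes the demand-weighted sum of
#' assigned distances, the p-median objective Z.
#'
#' @param instance a `pmedian_instance`.
#' @param facilities integer vector of `p` distinct candidate indices.
#' @param dmat optional precomputed distance matrix from [pairwise_distances()].
#' @return an object of class `pmedian_solution`: list with `facilities`
#'   (sorted indices), `assignment` (length-n integer vector of facility
#'   indices), `distances` (assigned distances) and `objective`.
#' @export
evaluate_solution <- function(instance, facilities, dmat = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"))
  facilities <- sort(unique(as.integer(facilities)))
  if (length(facilities) != instance$p)
    stop("cardinality violation: |facilities| must equal p")
  if (!all(facilities %in% instance$candidates))
    stop("facilities must be candidate sites")
  d <- instance_dmat(instance, dmat)
  ev <- cpp_evaluate(d, instance$points$weight, facilities - 1L)
  new_solution(facilities, ev$assign + 1L, ev$dist, ev$objective)
}

new_solution <- function(facilities, assignment, distances, objective) {
  structure(list(facilities = as.integer(facilities),
                 assignment = as.integer(assignment),
                 distances = as.numeric(distances),
                 objective = as.numeric(objective)),
            class = "pmedian_solution")
}

#' @export
print.pmedian_solution <- function(x, ...) {
  cat(sprintf("p-median solution: p = %d facilities, Z = %.6g\n",
              length(x$facilities), x$objective))
  invisible(x)
}

#' Relative cost of an objective against a best-known baseline
#'
#' @param objective an objective value Z.
#' @param best_known the best-known objective for the same instance; must be
#'   positive.
#' @return `100 * objective / best_known` (percent).
#' @export
relative_cost <- function(objective, best_known) {
  if (!is.numeric(best_known) || best_known <= 0) stop("invalid baseline")
  100 * objective / best_known
}

#' Exact optimum by exhaustive enumeration (oracle)
#'
#' Enumerates every size-`p` subset of the candidate set and returns the one
#' minimising Z (first subset in lexicographic order on ties). Intended as a
#' reference oracle for small instances.
#'
#' @param instance a `pmedian_instance`.
#' @param guard maximum number of subsets that will be enumerated.
#' @param dmat optional precomputed distance matrix.
#' @return a `pmedian_solution`.
#' @export
brute_force_optimum <- function(instance, guard = 1e6, dmat = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"))
  n_subsets <- choose(length(instance$candidates), instance$p)
  if (n_subsets > guard) stop("instance too large for oracle")
  d <- instance_dmat(instance, dmat)
  bf <- cpp_brute_force(d, instance$points$weight, instance$candidates - 1L,
                        instance$p)
  evaluate_solution(instance, bf$facilities + 1L, dmat = d)
}
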