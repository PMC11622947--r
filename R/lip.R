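#' Build the linear integer program for a p-median instance
#'
#' The discrete p-median LIP has binary location variables `X_j` over the
#' candidate sites and binary assignment variables `Y_ij` over destination x
#' candidate pairs, minimising the demand-weighted assignment distance
#' `sum_i sum_j w_i Y_ij d_ij` subject to: each destination assigned to
#' exactly one facility (block 1, n constraints), exactly `p` facilities open
#' (block 2, one constraint), and `Y_ij <= X_j` linking assignments to open
#' facilities (block 3, n x |candidates| constraints). The model object is a
#' symbolic description handed to a solver backend by [solve_exact()].
#'
#' @param instance a `pmedian_instance`.
#' @param dmat optional precomputed distance matrix.
#' @return a `lip_model` list: `instance`, `cost` (n x |cand| matrix of
#'   `w_i d_ij`), `p`, `n_x`, `n_y` (variable counts) and `n_constraints`
#'   (per-block and total counts).
#' @export
build_lip <- function(instance, dmat = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"))
  n <- nrow(instance$points)
  cand <- instance$candidates
  if (instance$p > length(cand)) stop("infeasible cardinality")
  d <- instance_dmat(instance, dmat)
  cost <- d[, cand, drop = FALSE] * instance$points$weight
  structure(list(instance = instance, cost = cost, p = instance$p,
                 dmat = d,
                 n_x = length(cand), n_y = n * length(cand),
                 n_constraints = list(assignment = n, cardinality = 1L,
                                      linking = n * length(cand),
                                      total = n + 1L + n * length(cand))),
            class = "lip_model")
}

#' @export
print.lip_model <- function(x, ...) {
  cat(sprintf("p-median LIP: %d X-variables, %d Y-variables, %d constraints, p = %d\n",
              x$n_x, x$n_y, x$n_constraints$total, x$p))
  invisible(x)
}

#' Solve the p-median LIP exactly
#'
#' Dispatches the model to a solver backend. The packaged backend
#' (`"branch_bound"`) is an exact depth-first branch-and-bound over the
#' location variables: at each node the lower bound is the demand-weighted sum
#' of each destination's best distance to any opened-or-still-available
#' candidate, which relaxes the cardinality constraint and is therefore valid;
#' a greedy-addition incumbent seeds the search. Additional backends can be
#' registered under new names via the `backend` argument contract
#' (build -> solve -> extract).
#'
#' @param model a `lip_model` from [build_lip()].
#' @param time_limit wall-clock budget in seconds (negative = unlimited; 0
#'   returns the greedy incumbent unproven).
#' @param backend backend name; only `"branch_bound"` is packaged.
#' @return a `pmedian_solution` with attribute `exact_info`: list with
#'   `optimal` (logical), `bound` (valid global lower bound) and `nodes`.
#' @export
solve_exact <- function(model, time_limit = -1, backend = "branch_bound") {
  stopifnot(inherits(model, "lip_model"))
  if (!identical(backend, "branch_bound"))
    stop("no MILP backend configured: '", backend, "'")
  inst <- model$instance
  bb <- cpp_branch_bound(model$dmat, inst$points$weight,
                         inst$candidates - 1L, inst$p, as.numeric(time_limit))
  sol <- evaluate_solution(inst, bb$facilities + 1L, dmat = model$dmat)
  attr(sol, "exact_info") <- list(optimal = bb$optimal, bound = bb$bound,
                                  nodes = bb$nodes)
  sol
}
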