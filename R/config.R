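#' Configuration for the EM-FI pipeline
#'
#' @param cmax largest mixture order tried by the BIC sweep.
#' @param alpha significance level of the quadrat homogeneity test.
#' @param milp_max_n,milp_max_p a subproblem is solved exactly (branch and
#'   bound over the LIP) only when its destination count and facility count
#'   are both at or below these thresholds; larger subproblems use fast
#'   interchange. Defaults reflect where the packaged exact solver is
#'   comfortably fast on one core.
#' @param milp_time_limit per-subproblem exact-solve budget, seconds; on
#'   timeout the subproblem falls back to warm-started fast interchange.
#' @param workers number of concurrent subproblem solves (forked processes).
#'   Results are independent of `workers`: every subproblem derives its own
#'   seed from the master seed and its demand rank.
#' @param improve_mode conquer-stage refinement: `"none"` (reassignment
#'   only), `"global_fi"` (global fast interchange warm-started at the
#'   reassignment solution), or `"distance_decomposition"` (iterative k-means
#'   re-decomposition of the current facilities).
#' @param seed master seed; all pipeline randomness derives from it.
#' @param em_tol,em_n_init,em_max_iter EM convergence tolerance, restarts and
#'   iteration cap (see [fit_gmm()]).
#' @param chi2_cells grid cells for the homogeneity test (`NULL` = per-subregion
#'   default `max(16, n_sub)`).
#' @param ddc_kmax largest k swept by the Davies-Bouldin selection in the
#'   distance decomposition (`NULL` = `min(20, ceiling(sqrt(p)))`).
#' @param ddc_stall_tol relative objective change treated as "unchanged"
#'   between consecutive distance-decomposition iterations.
#' @param fi_max_iterations safety cap on fast-interchange iterations
#'   (negative = unlimited).
#' @return an `emfi_config` list.
#' @export
emfi_config <- function(cmax = 20L, alpha = 0.05,
                        milp_max_n = 60L, milp_max_p = 6L,
                        milp_time_limit = 20,
                        workers = 1L,
                        improve_mode = c("none", "global_fi",
                                         "distance_decomposition"),
                        seed = 1L,
                        em_tol = 1e-4, em_n_init = 5L, em_max_iter = 200L,
                        chi2_cells = NULL,
                        ddc_kmax = NULL, ddc_stall_tol = 1e-9,
                        fi_max_iterations = -1L) {
  improve_mode <- match.arg(improve_mode)
  stopifnot(workers >= 1L, milp_max_n > 0L, milp_max_p > 0L, cmax >= 2L)
  structure(list(cmax = as.integer(cmax), alpha = alpha,
                 milp_max_n = as.integer(milp_max_n),
                 milp_max_p = as.integer(milp_max_p),
                 milp_time_limit = milp_time_limit,
                 workers = as.integer(workers), improve_mode = improve_mode,
                 seed = as.integer(seed), em_tol = em_tol,
                 em_n_init = as.integer(em_n_init),
                 em_max_iter = as.integer(em_max_iter),
                 chi2_cells = chi2_cells,
                 ddc_kmax = ddc_kmax, ddc_stall_tol = ddc_stall_tol,
                 fi_max_iterations = as.integer(fi_max_iterations)),
            class = "emfi_config")
}

# deterministic per-subproblem seed from the master seed and the subproblem's
# rank in decreasing-demand order; independent of worker scheduling
derive_seed <- function(master, rank) {
  as.integer((as.numeric(master) %% 65011 * 10007 + rank * 7919 + 13) %% 2147483647)
}
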