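#' Apportion facilities to subregions in proportion to demand
#'
#' Each subregion receives `floor(p * demand_share)` facilities; the leftover
#' is handed out one at a time in decreasing order of subregion demand
#' (cycling, ties broken by subregion index). Counts are capped at the
#' subregion member count, with any overflow redistributed down the demand
#' order, so `sum(p_sub) == p` always.
#'
#' @param demands numeric vector of subregion total demands (positive).
#' @param p total facility count.
#' @param capacities member count per subregion (cap on `p_sub`); default
#'   unbounded.
#' @return integer vector of per-subregion facility counts.
#' @export
apportion_facilities <- function(demands, p, capacities = NULL) {
  q <- length(demands)
  stopifnot(q >= 1L, p >= 1L, all(demands > 0))
  if (is.null(capacities)) capacities <- rep.int(p, q)
  if (p > sum(capacities)) stop("infeasible cardinality: p exceeds capacity")
  share <- demands / sum(demands)
  p_sub <- pmin(as.integer(floor(p * share)), capacities)
  ord <- order(-demands, seq_len(q))
  i <- 1L
  guard <- 0L
  while (sum(p_sub) < p) {
    s <- ord[(i - 1L) %% q + 1L]
    if (p_sub[s] < capacities[s]) p_sub[s] <- p_sub[s] + 1L
    i <- i + 1L
    guard <- guard + 1L
    if (guard > p * q + q) stop("apportionment failed to converge")
  }
  p_sub
}

#' Choose the subproblem solver
#'
#' Exact branch and bound when the subproblem is small enough on both axes,
#' fast interchange otherwise; degenerate subproblems (`p_sub = 0`) get no
#' solver.
#'
#' @param n_sub,p_sub subproblem destination and facility counts.
#' @param config an [emfi_config()].
#' @return `"MILP"`, `"FI"` or `"none"`.
#' @export
choose_subsolver <- function(n_sub, p_sub, config) {
  if (p_sub == 0L) return("none")
  if (n_sub <= config$milp_max_n && p_sub <= config$milp_max_p) "MILP" else "FI"
}

# Solve one subproblem on its own members; returns global point indices.
solve_one_subproblem <- function(instance, members, p_sub, config, seed,
                                 warm_start = NULL, dmat = NULL) {
  if (p_sub == 0L) return(integer(0))
  if (p_sub >= length(members)) return(sort(members))
  pts <- instance$points[members, , drop = FALSE]
  sub <- pmedian_instance(pts, p = p_sub)
  sub_d <- if (is.null(dmat)) pairwise_distances(sub) else
    dmat[members, members, drop = FALSE]
  solver <- choose_subsolver(length(members), p_sub, config)
  local_warm <- if (!is.null(warm_start)) match(warm_start, members)
  if (identical(solver, "MILP")) {
    sol <- solve_exact(build_lip(sub, dmat = sub_d),
                       time_limit = config$milp_time_limit)
    if (!attr(sol, "exact_info")$optimal)
      sol <- fast_interchange(sub, sol$facilities,
                              max_iterations = config$fi_max_iterations,
                              dmat = sub_d)
  } else {
    init <- if (!is.null(local_warm)) sort(local_warm) else
      random_initial_solution(sub, seed = seed)
    sol <- fast_interchange(sub, init,
                            max_iterations = config$fi_max_iterations,
                            dmat = sub_d)
  }
  sort(members[sol$facilities])
}

#' Solve the apportioned subproblems concurrently
#'
#' Each subregion is solved as an independent p-median problem over its own
#' members. Per-subproblem seeds derive from the master seed and the
#' subregion's demand rank, so results do not depend on `workers` or
#' scheduling.
#'
#' @param instance a `pmedian_instance`.
#' @param labels per-point subproblem id in `1..q`.
#' @param p_subs per-subproblem facility counts, `sum(p_subs)` = `p`.
#' @param config an [emfi_config()].
#' @param warm_starts optional list of per-subproblem warm-start facility
#'   sets (global indices).
#' @param dmat optional precomputed full distance matrix.
#' @return list of `q` sorted global facility index vectors.
#' @export
solve_subproblems <- function(instance, labels, p_subs, config,
                              warm_starts = NULL, dmat = NULL) {
  q <- length(p_subs)
  members <- lapply(seq_len(q), function(s) which(labels == s))
  demands <- vapply(members, function(m) sum(instance$points$weight[m]),
                    numeric(1))
  rank <- match(seq_len(q), order(-demands, seq_len(q)))
  seeds <- vapply(seq_len(q), function(s) derive_seed(config$seed, rank[s]),
                  integer(1))
  worker <- function(s) {
    ws <- if (is.null(warm_starts)) NULL else warm_starts[[s]]
    solve_one_subproblem(instance, members[[s]], p_subs[s], config, seeds[s],
                         warm_start = ws, dmat = dmat)
  }
  if (config$workers > 1L && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(seq_len(q), worker,
                              mc.cores = config$workers,
                              mc.preschedule = TRUE)
    bad <- vapply(out, inherits, logical(1), "try-error")
    if (any(bad)) stop("subproblem ", which(bad)[1], " failed: ", out[[which(bad)[1]]])
    out
  } else {
    lapply(seq_len(q), worker)
  }
}

#' Conquer step: union the subproblem facilities and reassign globally
#'
#' @param instance a `pmedian_instance`.
#' @param facility_sets list of per-subproblem facility index vectors whose
#'   union must have size `p`.
#' @param dmat optional precomputed distance matrix.
#' @return a `pmedian_solution` (the reassignment-stage solution).
#' @export
conquer_reassign <- function(instance, facility_sets, dmat = NULL) {
  fac <- sort(unique(unlist(facility_sets)))
  if (length(fac) != instance$p)
    stop("apportionment breach: union of subproblem facilities has size ",
         length(fac), ", expected p = ", instance$p)
  evaluate_solution(instance, fac, dmat = dmat)
}

#' Improvement step: global fast interchange from a warm start
#'
#' @param instance a `pmedian_instance`.
#' @param solution a `pmedian_solution` to warm-start from.
#' @param config an [emfi_config()] (for the iteration cap).
#' @param dmat optional precomputed distance matrix.
#' @return a `pmedian_solution` with objective no larger than the input's.
#' @export
improve_global <- function(instance, solution, config = emfi_config(),
                           dmat = NULL) {
  fast_interchange(instance, solution$facilities,
                   max_iterations = config$fi_max_iterations, dmat = dmat)
}

#' Run the full EM-FI divide-and-conquer pipeline
#'
#' Pipeline: (1) fit bivariate Gaussian mixtures for `c = 2..cmax` and keep
#' the minimum-BIC labelling; (2) classify subregions by density and the
#' quadrat homogeneity test, dissolving non-clustered subregions into the
#' dense ones; (3) apportion facilities to the `q` surviving subregions in
#' proportion to demand; (4) solve the subproblems concurrently (exact branch
#' and bound or fast interchange); (5) union the facilities and reassign all
#' destinations globally (the *reassignment* solution); (6) optionally refine
#' by global fast interchange or iterative distance-based re-decomposition.
#' When the decomposition collapses (no clustered subregion, or `q = 1`) the
#' pipeline falls back to a global solve: distance-based decomposition when
#' `improve_mode = "distance_decomposition"`, a single seeded global fast
#' interchange otherwise.
#'
#' @param instance a `pmedian_instance`.
#' @param config an [emfi_config()].
#' @param best_known optional baseline objective for relative-cost reporting.
#' @return an `emfi_result` list: `solution` (final), `reassignment`
#'   (pre-improvement solution), `report` (method, objective,
#'   `relative_cost_percent`, iterations, wall time, seed, `k`, `q`,
#'   `fallback`, per-stage timings) and `decomposition` (labels, subregion
#'   table, BIC table) when the density decomposition ran.
#' @export
run_em_fi <- function(instance, config = emfi_config(), best_known = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"),
            inherits(config, "emfi_config"))
  t_start <- proc.time()[["elapsed"]]
  stage <- list()
  tic <- function() proc.time()[["elapsed"]]
  dmat <- pairwise_distances(instance)

  t0 <- tic()
  dec <- tryCatch(
    select_component_model(instance, c_max = min(config$cmax,
                                                 nrow(instance$points) - 1L),
                           seed = config$seed, tol = config$em_tol,
                           max_iter = config$em_max_iter,
                           n_init = config$em_n_init),
    error = function(e) e)
  stage$decomposition <- tic() - t0

  k <- NA_integer_; q <- NA_integer_
  fallback <- NA_character_
  classification <- NULL; merged <- NULL; labels <- NULL

  if (!inherits(dec, "error")) {
    k <- dec$k
    t0 <- tic()
    merged <- tryCatch({
      classification <- classify_subregions(instance, dec$labeling$label,
                                            alpha = config$alpha,
                                            n_cells = config$chi2_cells)
      merge_nonclustered(instance, dec$labeling$label, classification)
    }, emfi_fully_homogeneous = function(e) e, error = function(e) e)
    stage$merge <- tic() - t0
    if (!inherits(merged, "error") && merged$q > 1L) {
      q <- merged$q
      labels <- merged$labels
    }
  }

  if (is.null(labels)) {
    # decomposition collapsed: solve globally
    if (inherits(merged, "condition") || inherits(dec, "error")) q <- 1L
    else if (!is.null(merged$q)) q <- merged$q
    t0 <- tic()
    if (config$improve_mode == "distance_decomposition") {
      fallback <- "distance_decomposition"
      res <- ddc_from_scratch(instance, config, dmat = dmat)
      reassignment <- res$initial
      final <- res$solution
      ddc_trace <- res$trace
    } else {
      # q = 1: the whole instance is the single subproblem, solved by the
      # scale-appropriate subsolver, then improved per improve_mode
      fallback <- "global_fi"
      sets <- solve_subproblems(instance, rep(1L, nrow(instance$points)),
                                instance$p, config, dmat = dmat)
      reassignment <- conquer_reassign(instance, sets, dmat = dmat)
      final <- if (config$improve_mode == "global_fi")
        improve_global(instance, reassignment, config, dmat = dmat)
      else reassignment
      ddc_trace <- NULL
    }
    stage$conquer <- tic() - t0
  } else {
    t0 <- tic()
    members <- split(seq_len(nrow(instance$points)), labels)
    demands <- vapply(members, function(m) sum(instance$points$weight[m]),
                      numeric(1))
    caps <- lengths(members)
    p_subs <- apportion_facilities(demands, instance$p, capacities = caps)
    if (max(caps) > 0.5 * nrow(instance$points))
      warning("one subproblem holds more than half of all destinations; ",
              "it may dominate the run time")
    stage$apportion <- tic() - t0
    t0 <- tic()
    sets <- solve_subproblems(instance, labels, p_subs, config, dmat = dmat)
    stage$subproblems <- tic() - t0
    t0 <- tic()
    reassignment <- conquer_reassign(instance, sets, dmat = dmat)
    stage$conquer <- tic() - t0
    t0 <- tic()
    ddc_trace <- NULL
    final <- switch(config$improve_mode,
      none = reassignment,
      global_fi = improve_global(instance, reassignment, config, dmat = dmat),
      distance_decomposition = {
        res <- iterate_distance_decomposition(instance, reassignment, config,
                                              dmat = dmat)
        ddc_trace <- res$trace
        res$solution
      })
    stage$improvement <- tic() - t0
  }

  fi_stats <- attr(final, "fi_stats")
  report <- list(
    method = paste0("em_fi:", config$improve_mode,
                    if (!is.na(fallback)) paste0(" (fallback: ", fallback, ")") else ""),
    objective = final$objective,
    relative_cost_percent = if (!is.null(best_known))
      relative_cost(final$objective, best_known) else NA_real_,
    iterations = if (!is.null(fi_stats)) fi_stats$iterations else NA_integer_,
    wall_time = proc.time()[["elapsed"]] - t_start,
    seed = config$seed, k = k, q = q, fallback = fallback,
    stage_times = stage)
  structure(list(solution = final, reassignment = reassignment,
                 report = report, ddc_trace = ddc_trace,
                 decomposition = if (!inherits(dec, "error"))
                   list(k = k, q = q, labels = labels,
                        mixture_labels = dec$labeling$label,
                        classification = classification,
                        bic_table = dec$bic_table) else NULL),
            class = "emfi_result")
}

#' @export
print.emfi_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("EM-FI result (%s): Z = %.6g", r$method, r$objective))
  if (!is.na(r$relative_cost_percent))
    cat(sprintf(", relative cost = %.2f%%", r$relative_cost_percent))
  cat(sprintf("\nk = %s mixture components -> q = %s subproblems; %.2fs\n",
              r$k, r$q, r$wall_time))
  invisible(x)
}
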