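#' Random-restart fast-interchange objectives
#'
#' Runs `n_restarts` independent seeded fast-interchange solves and returns
#' their final objectives. The minimum over such restarts (optionally together
#' with exact solves and other heuristic runs) is the best-known baseline used
#' for relative-cost reporting.
#'
#' @param instance a `pmedian_instance`.
#' @param n_restarts number of restarts.
#' @param seed base seed; restart `r` uses `seed * 1000 + r`.
#' @param dmat optional precomputed distance matrix.
#' @return numeric vector of `n_restarts` objectives.
#' @export
fi_restarts <- function(instance, n_restarts = 30L, seed = 1L, dmat = NULL) {
  d <- instance_dmat(instance, dmat)
  vapply(seq_len(n_restarts), function(r) {
    init <- random_initial_solution(instance,
                                    seed = as.integer(seed) * 1000L + r)
    fast_interchange(instance, init, dmat = d)$objective
  }, numeric(1))
}
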