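#' Configuration for the synthetic instance generator
#'
#' The generator emulates the construction of census-block-group-like demand
#' surfaces: atomic demand units are scattered over a fine grid according to a
#' chosen spatial layout, then merged into destinations whose target demands
#' are drawn from a normal distribution (mean 1500, sd 400, truncated below at
#' one unit), with the facility count set to a fixed fraction of the number of
#' destinations (default p = n/4).
#'
#' @param layout one of `"clustered"` (a uniform mixture of
#'   `n_gen_clusters` bivariate Gaussian blobs), `"homogeneous"` (uniform over
#'   the grid) or `"centered"` (a single central Gaussian with spread
#'   `grid_side / 8`).
#' @param grid_side cells per side of the fine grid.
#' @param total_demand total number of atomic demand units to scatter.
#' @param n_gen_clusters number of generator blobs for the clustered layout.
#' @param cluster_spread blob standard deviation, in grid cells.
#' @param separation_factor minimum pairwise blob-center separation, in units
#'   of `cluster_spread`.
#' @param demand_mean,demand_sd parameters of the per-destination target
#'   demand distribution.
#' @param p_fraction facility count as a fraction of the destination count.
#' @param seed integer seed; the whole generator is deterministic given it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(layout = c("clustered", "centered", "homogeneous"),
                             grid_side = 256L,
                             total_demand = 600000L,
                             n_gen_clusters = 8L,
                             cluster_spread = 6,
                             separation_factor = 10,
                             demand_mean = 1500,
                             demand_sd = 400,
                             p_fraction = 0.25,
                             seed = 1L) {
  layout <- match.arg(layout)
  if (!is.numeric(total_demand) || total_demand <= 0)
    stop("invalid config: total_demand must be positive")
  if (demand_mean <= 0) stop("invalid config: demand_mean must be positive")
  if (p_fraction <= 0 || p_fraction >= 1)
    stop("invalid config: p_fraction must lie in (0, 1)")
  if (separation_factor <= 0)
    stop("invalid config: separation_factor must be positive")
  structure(list(layout = layout, grid_side = as.integer(grid_side),
                 total_demand = as.integer(round(total_demand)),
                 n_gen_clusters = as.integer(n_gen_clusters),
                 cluster_spread = cluster_spread,
                 separation_factor = separation_factor,
                 demand_mean = demand_mean, demand_sd = demand_sd,
                 p_fraction = p_fraction, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Blob centers: uniform rejection sampling with a minimum-separation
# constraint, kept away from the grid edge by two standard deviations.
place_blob_centers <- function(config) {
  side <- config$grid_side
  margin <- min(2 * config$cluster_spread, side / 4)
  min_sep <- config$separation_factor * config$cluster_spread
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < config$n_gen_clusters) {
    cand <- stats::runif(2, margin, side - margin)
    ok <- nrow(centers) == 0 ||
      all(sqrt(colSums((t(centers) - cand)^2)) >= min_sep)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1L
    if (tries > 20000L)
      stop("cannot place ", config$n_gen_clusters,
           " blob centers at separation ", min_sep, " on a ", side, " grid")
  }
  unname(centers)
}

#' Scatter atomic demand units over the fine grid
#'
#' @param config a [synthetic_config()].
#' @return a `demand_units` list: `units` (a `total_demand` x 2 matrix of
#'   grid-cell-center coordinates), `label` (generator blob per unit for the
#'   clustered layout, `NA` otherwise), `centers` (blob centers) and `config`.
#' @export
scatter_demand_units <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  side <- config$grid_side
  m <- config$total_demand
  label <- rep(NA_integer_, m)
  centers <- NULL
  if (config$layout == "homogeneous") {
    xy <- cbind(sample.int(side, m, replace = TRUE) - 1L,
                sample.int(side, m, replace = TRUE) - 1L)
    xy <- xy + 0.5
  } else {
    if (config$layout == "clustered") {
      centers <- place_blob_centers(config)
      label <- sample.int(config$n_gen_clusters, m, replace = TRUE)
      mu <- centers[label, , drop = FALSE]
      sd <- config$cluster_spread
    } else { # centered: one broad Gaussian in the middle of the grid
      centers <- matrix(c(side / 2, side / 2), ncol = 2)
      mu <- centers[rep(1L, m), , drop = FALSE]
      sd <- side / 8
    }
    raw <- mu + matrix(stats::rnorm(2 * m, sd = sd), ncol = 2)
    cell <- pmin(pmax(floor(raw), 0), side - 1L)
    xy <- cell + 0.5
  }
  structure(list(units = unname(xy), label = label, centers = centers,
                 config = config),
            class = "demand_units")
}

#' Aggregate demand units into destinations
#'
#' Repeatedly draws a target demand from the truncated normal model, seeds a
#' destination at a randomly chosen unassigned unit, and absorbs the nearest
#' unassigned units until the target is met (or units run out). The
#' destination sits at the centroid of its absorbed units and its weight is
#' the number of units absorbed, so total demand is conserved exactly.
#'
#' @param units a `demand_units` object from [scatter_demand_units()].
#' @param config the same [synthetic_config()].
#' @return a `pmedian_instance` with `p = round(p_fraction * n)`; element
#'   `labels` carries the majority generator blob per destination (clustered
#'   layout only).
#' @export
aggregate_units_to_destinations <- function(units, config) {
  stopifnot(inherits(units, "demand_units"))
  if (nrow(units$units) < 1L) stop("empty instance")
  set.seed(config$seed + 1L)
  # collapse to occupied cells: units snapped to a cell are coincident
  key <- paste(units$units[, 1], units$units[, 2], sep = "_")
  cells <- !duplicated(key)
  cell_xy <- units$units[cells, , drop = FALSE]
  idx <- match(key, key[cells])
  rem <- tabulate(idx, nbins = nrow(cell_xy))
  cell_lab <- rep(NA_integer_, nrow(cell_xy))
  if (!all(is.na(units$label))) {
    nlab <- max(units$label)
    cnt <- vapply(seq_len(nlab), function(b)
      tabulate(idx[units$label == b], nbins = nrow(cell_xy)), integer(nrow(cell_xy)))
    cell_lab <- max.col(cnt, ties.method = "first")
  }
  dest <- list()
  while (sum(rem) > 0L) {
    target <- max(1L, as.integer(round(stats::rnorm(1, config$demand_mean,
                                                    config$demand_sd))))
    active <- which(rem > 0L)
    seed_cell <- if (length(active) == 1L) active else
      sample(active, 1L, prob = rem[active])
    d2 <- (cell_xy[active, 1] - cell_xy[seed_cell, 1])^2 +
          (cell_xy[active, 2] - cell_xy[seed_cell, 2])^2
    ord <- active[order(d2, active)]
    cum <- cumsum(rem[ord])
    last <- which(cum >= target)[1L]
    if (is.na(last)) last <- length(ord)
    take_cells <- ord[seq_len(last)]
    take <- rem[take_cells]
    overshoot <- sum(take) - target
    if (overshoot > 0L) take[last] <- take[last] - overshoot
    w <- sum(take)
    centroid <- colSums(cell_xy[take_cells, , drop = FALSE] * take) / w
    lab <- NA_integer_
    if (!all(is.na(cell_lab))) {
      tl <- tapply(take, cell_lab[take_cells], sum)
      lab <- as.integer(names(tl)[which.max(tl)])
    }
    rem[take_cells] <- rem[take_cells] - take
    dest[[length(dest) + 1L]] <- c(centroid, w, lab)
  }
  dd <- do.call(rbind, dest)
  n <- nrow(dd)
  pts <- data.frame(id = sprintf("d%04d", seq_len(n)),
                    x = dd[, 1], y = dd[, 2], weight = dd[, 3])
  inst <- pmedian_instance(pts, p = max(1L, round(config$p_fraction * n)))
  inst$labels <- as.integer(dd[, 4])
  inst$gen_centers <- units$centers
  inst$config <- config
  inst
}

#' Generate a complete synthetic p-median instance
#'
#' Composition of [scatter_demand_units()] and
#' [aggregate_units_to_destinations()]; fully deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a `pmedian_instance` (with generator blob labels for the clustered
#'   layout in `$labels`).
#' @export
generate_instance <- function(config) {
  aggregate_units_to_destinations(scatter_demand_units(config), config)
}
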