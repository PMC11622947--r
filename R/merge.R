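# Subregion classification: a subregion is a candidate subproblem only when
# it is dense (demand density >= the region's) AND spatially heterogeneous
# (the quadrat chi-squared test rejects uniform scatter). Everything else is
# dissolved into the nearest dense subregion.

# polygon area of the convex hull of a point set; 0 when degenerate
hull_area <- function(coords) {
  co <- unique(coords_of(coords))
  if (nrow(co) < 3L) return(0)
  h <- grDevices::chull(co)
  xs <- co[h, 1]; ys <- co[h, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Demand density of a subregion
#'
#' Total demand divided by the convex-hull area of the member coordinates.
#' Subregions with a degenerate hull (fewer than three distinct points, or
#' collinear members) have zero area and are reported with `NA` density;
#' classification treats them as sparse.
#'
#' @param subregion_points member coordinates (matrix or data.frame with
#'   `x`, `y`).
#' @param weights member demand weights.
#' @return list with `total_demand`, `area` and `density`.
#' @export
subregion_density <- function(subregion_points, weights) {
  co <- coords_of(subregion_points)
  if (nrow(co) < 1L) stop("empty subregion")
  total <- sum(weights)
  area <- hull_area(co)
  list(total_demand = total, area = area,
       density = if (area > 0) total / area else NA_real_)
}

#' Quadrat chi-squared test of spatial homogeneity
#'
#' Overlays a near-square grid of `n_cells` equal cells on the bounding box of
#' the member coordinates and compares the observed cell-occupancy frequency
#' `F(i)` (number of cells holding exactly `i` members) with the binomial
#' expectation under uniform scatter, `E(i) = N * C(n_sub, i) p_cell^i
#' (1 - p_cell)^(n_sub - i)` with `p_cell = 1/N`. The statistic
#' `sum_i (E(i) - F(i))^2 / E(i)` is referred to a chi-squared distribution
#' with `n_sub` degrees of freedom (a deliberately conservative convention),
#' rejecting homogeneity (i.e. declaring heterogeneity) when the tail
#' probability falls below `alpha`.
#'
#' The requested cell count is arranged as an `nr x nc` grid with
#' `nr = round(sqrt(n_cells))`, so the effective `N = nr * nc` may differ
#' slightly from the request; the occupancy sum is truncated at the first `i`
#' whose binomial tail contributes less than `1e-9` expected cells, with the
#' residual mass folded into the last bin so that `sum E(i) = N` exactly.
#'
#' @param member_coords member coordinates (matrix or data.frame `x`, `y`).
#' @param n_cells requested number of grid cells (default
#'   `max(16, n_sub)`, giving average occupancy of about one).
#' @param alpha significance level (default 0.05).
#' @param extent grid extent as `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of `member_coords`. Subregion classification passes the
#'   whole-region extent here, so that a subregion concentrated in a small
#'   part of the region registers as heterogeneous even when its members are
#'   evenly spread among themselves.
#' @return a `heterogeneity_result` list: `n_sub`, `n_cells`, `p_cell`,
#'   `expected`, `observed` (aligned occupancy bins, last bin = "or more"),
#'   `chi2`, `dof`, `p_value`, `reject`, `alpha`.
#' @export
heterogeneity_test <- function(member_coords, n_cells = NULL, alpha = 0.05,
                               extent = NULL) {
  co <- coords_of(member_coords)
  n_sub <- nrow(co)
  if (n_sub < 1L) stop("empty subregion")
  if (is.null(n_cells)) n_cells <- max(16L, n_sub)
  if (n_cells < 2L) stop("need at least 2 cells")
  if (is.null(extent)) extent <- c(range(co[, 1]), range(co[, 2]))
  nr <- max(1L, as.integer(round(sqrt(n_cells))))
  nc <- max(1L, as.integer(round(n_cells / nr)))
  N <- nr * nc
  cx <- bin_index(co[, 1], nc, extent[1], extent[2])
  cy <- bin_index(co[, 2], nr, extent[3], extent[4])
  occ <- tabulate(cy * nc + cx + 1L, nbins = N)

  p_cell <- 1 / N
  # truncate where the remaining expected mass drops below 1e-9 cells
  tail_mass <- N * stats::pbinom(0:n_sub - 1L, n_sub, p_cell,
                                 lower.tail = FALSE)
  imax <- which(tail_mass < 1e-9)[1L]
  imax <- if (is.na(imax)) n_sub else min(n_sub, imax - 1L)
  imax <- max(imax, 1L)
  E <- N * stats::dbinom(0:imax, n_sub, p_cell)
  E[imax + 1L] <- N * stats::pbinom(imax - 1L, n_sub, p_cell,
                                    lower.tail = FALSE)
  FF <- tabulate(pmin(occ, imax) + 1L, nbins = imax + 1L)
  keep <- E > 0 | FF > 0
  chi2 <- sum((E[keep] - FF[keep])^2 / pmax(E[keep], 1e-300))
  p_value <- stats::pchisq(chi2, df = n_sub, lower.tail = FALSE)
  structure(list(n_sub = n_sub, n_cells = N, p_cell = p_cell,
                 expected = E, observed = FF, chi2 = chi2, dof = n_sub,
                 p_value = p_value, reject = p_value < alpha, alpha = alpha),
            class = "heterogeneity_result")
}

# equal-width bins over [lo, hi]; degenerate range -> single bin 0
bin_index <- function(v, nbins, lo = min(v), hi = max(v)) {
  if (hi <= lo) return(rep(0L, length(v)))
  pmin(pmax(as.integer(floor((v - lo) / (hi - lo) * nbins)), 0L), nbins - 1L)
}

#' Classify mixture subregions as clustered or not
#'
#' A subregion is *sparse* when its demand density is strictly below the
#' region-wide density (total demand over the convex hull of all points), and
#' *homogeneous* when [heterogeneity_test()] fails to reject uniform scatter.
#' Only subregions that are neither — dense and heterogeneous — are kept as
#' independent subproblems.
#'
#' @param instance a `pmedian_instance`.
#' @param labels integer subregion label per point (e.g. a mixture labelling).
#' @param alpha significance level for the homogeneity test.
#' @param n_cells grid cells for the test (default per subregion:
#'   `max(16, n_sub)`).
#' @return a data.frame with one row per subregion: `label`, `n_members`,
#'   `total_demand`, `area`, `density`, `is_sparse`, `is_homogeneous`,
#'   `is_clustered`, `centroid_x`, `centroid_y`; attribute `region_density`.
#' @export
classify_subregions <- function(instance, labels, alpha = 0.05,
                                n_cells = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"))
  pts <- instance$points
  stopifnot(length(labels) == nrow(pts))
  reg_area <- hull_area(pts)
  region_density <- if (reg_area > 0) sum(pts$weight) / reg_area else Inf
  region_extent <- c(range(pts$x), range(pts$y))
  ids <- sort(unique(labels))
  rows <- lapply(ids, function(l) {
    m <- which(labels == l)
    dens <- subregion_density(pts[m, ], pts$weight[m])
    degenerate <- is.na(dens$density)
    sparse <- degenerate || dens$density < region_density
    het <- heterogeneity_test(pts[m, ], n_cells = n_cells, alpha = alpha,
                              extent = region_extent)
    data.frame(label = l, n_members = length(m),
               total_demand = dens$total_demand, area = dens$area,
               density = dens$density,
               is_sparse = sparse, is_homogeneous = !het$reject,
               is_clustered = !sparse && het$reject,
               centroid_x = mean(pts$x[m]), centroid_y = mean(pts$y[m]))
  })
  out <- do.call(rbind, rows)
  attr(out, "region_density") <- region_density
  out
}

#' Dissolve non-clustered subregions into the clustered ones
#'
#' Every point belonging to a sparse or homogeneous subregion is reassigned to
#' the clustered subregion with the nearest centroid (centroids frozen at
#' their pre-merge values), reducing `k` subregions to `q` subproblems that
#' still partition all points.
#'
#' @param instance a `pmedian_instance`.
#' @param labels subregion label per point.
#' @param classification the data.frame from [classify_subregions()].
#' @return list with `labels` (per-point subproblem id in `1..q`), `q`, and
#'   `kept` (original labels of the clustered subregions, in id order).
#'   Throws a condition of class `emfi_fully_homogeneous` when no subregion is
#'   clustered.
#' @export
merge_nonclustered <- function(instance, labels, classification) {
  keep <- classification$label[classification$is_clustered]
  if (length(keep) == 0L)
    stop(structure(class = c("emfi_fully_homogeneous", "error", "condition"),
                   list(message = "fully homogeneous region: no clustered subregion",
                        call = sys.call())))
  cen <- as.matrix(classification[classification$is_clustered,
                                  c("centroid_x", "centroid_y")])
  new_lab <- match(labels, keep)
  move <- which(is.na(new_lab))
  if (length(move)) {
    px <- instance$points$x[move]; py <- instance$points$y[move]
    d2 <- outer(px, cen[, 1], "-")^2 + outer(py, cen[, 2], "-")^2
    new_lab[move] <- max.col(-d2, ties.method = "first")
  }
  list(labels = new_lab, q = length(keep), kept = keep)
}
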