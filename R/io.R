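#' Read a p-median instance from CSV
#'
#' Expected header: `id,x,y,demand` (one row per demand point). Row order is
#' preserved as index order. Validation failures name the offending row or
#' id.
#'
#' @param path CSV file path.
#' @param p facility count for the instance; when `NULL`, taken from an
#'   optional `p` column comment is not supported — supply it explicitly
#'   (defaults to `round(n / 4)`).
#' @return a `pmedian_instance`.
#' @export
read_instance <- function(path, p = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "x", "y", "demand")
  if (!all(req %in% names(df)))
    stop("instance CSV must have columns id,x,y,demand")
  for (col in c("x", "y", "demand")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("row ", bad[1], ": column '", col, "' is not finite numeric")
    df[[col]] <- as.numeric(df[[col]])
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate id: ", dup[1])
  neg <- which(df$demand < 0)
  if (length(neg)) stop("row ", neg[1], " (id ", df$id[neg[1]],
                        "): negative demand")
  if (is.null(p)) p <- max(1L, round(nrow(df) / 4))
  pmedian_instance(data.frame(id = df$id, x = df$x, y = df$y,
                              weight = df$demand), p = p)
}

#' Write an instance to CSV
#'
#' @param instance a `pmedian_instance`.
#' @param path output CSV path (`id,x,y,demand`).
#' @param labels_path optional sidecar CSV for generator ground-truth labels.
#' @return `path`, invisibly.
#' @export
write_instance <- function(instance, path, labels_path = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"))
  df <- data.frame(id = instance$points$id, x = instance$points$x,
                   y = instance$points$y, demand = instance$points$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path) && !is.null(instance$labels))
    utils::write.csv(data.frame(id = instance$points$id,
                                label = instance$labels),
                     labels_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a solution as facility/assignment CSVs plus a summary JSON
#'
#' Writes `<stem>_facilities.csv` (`facility_id,x,y,p_rank`),
#' `<stem>_assignment.csv` (`dest_id,facility_id,distance,
#' weighted_distance`; the weighted distances sum to Z) and
#' `<stem>_summary.json` (method, Z, relative cost, q, k, seed, timings).
#'
#' @param stem output path stem.
#' @param instance the solved `pmedian_instance`.
#' @param solution a `pmedian_solution`.
#' @param report optional report list (from an `emfi_result` or built ad hoc).
#' @return named character vector of the three paths, invisibly.
#' @export
write_solution <- function(stem, instance, solution, report = NULL) {
  stopifnot(inherits(instance, "pmedian_instance"))
  if (!inherits(solution, "pmedian_solution") ||
      length(solution$facilities) == 0L)
    stop("unsolved instance")
  pts <- instance$points
  fac <- solution$facilities
  f_path <- paste0(stem, "_facilities.csv")
  a_path <- paste0(stem, "_assignment.csv")
  s_path <- paste0(stem, "_summary.json")
  utils::write.csv(data.frame(facility_id = pts$id[fac], x = pts$x[fac],
                              y = pts$y[fac], p_rank = seq_along(fac)),
                   f_path, row.names = FALSE, quote = FALSE)
  wd <- pts$weight * solution$distances
  utils::write.csv(data.frame(dest_id = pts$id,
                              facility_id = pts$id[solution$assignment],
                              distance = solution$distances,
                              weighted_distance = wd),
                   a_path, row.names = FALSE, quote = FALSE)
  summary <- c(list(objective = solution$objective, p = length(fac),
                    n = nrow(pts)),
               if (!is.null(report)) report[names(report) != "stage_times"],
               list(stage_times = if (!is.null(report)) report$stage_times))
  jsonlite::write_json(summary, s_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(facilities = f_path, assignment = a_path, summary = s_path))
}

#' Write facility service areas as GeoJSON
#'
#' One Point feature per facility and, for every facility with at least three
#' assigned destinations, one Polygon feature tracing the convex hull of its
#' service area. Properties carry the facility id and total served demand.
#'
#' @param path output GeoJSON path.
#' @param instance the solved `pmedian_instance`.
#' @param solution a `pmedian_solution`.
#' @return `path`, invisibly.
#' @export
write_service_geojson <- function(path, instance, solution) {
  stopifnot(inherits(instance, "pmedian_instance"),
            inherits(solution, "pmedian_solution"))
  pts <- instance$points
  features <- list()
  for (f in solution$facilities) {
    served <- which(solution$assignment == f)
    demand <- sum(pts$weight[served])
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(pts$x[f], pts$y[f])),
      properties = list(facility_id = pts$id[f], served_demand = demand,
                        n_served = length(served)))
    co <- unique(cbind(pts$x[served], pts$y[served]))
    if (nrow(co) >= 3L) {
      h <- grDevices::chull(co)
      ring <- co[c(h, h[1]), , drop = FALSE]
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(ring)),
                                                  function(i) ring[i, ]))),
        properties = list(facility_id = pts$id[f], served_demand = demand))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
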