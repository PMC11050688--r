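# Risk query for a planned field location: clip a circular window out of
# the area-wide risk map, report the class at the point, and list the
# previous-year sites whose outermost buffer reaches the point together
# with their distance and compass bearing — so the planner can see which
# directions the risk comes from.

#' Query the risk map at planned coordinates
#'
#' @param map A `rotadist_risk_map`.
#' @param previous The previous-year `rotadist_layer` the map was built
#'   from (used to identify risk sources).
#' @param x,y Planned-site coordinates in meters (same CRS as the map).
#' @param radius_m Clip radius in meters; default: outermost scheme distance
#'   plus a 500 m margin.
#' @param scheme Optional `risk_scheme` or per-crop scheme list used to
#'   decide which sources cover the point; defaults to the map's scheme.
#' @param segments Arc segments per quarter circle for the clip disc.
#' @return A `rotadist_query`: list with `point`, `radius_m`, `local_map`
#'   (the clipped `rotadist_risk_map`), `class_at_point` (`NA` outside all
#'   zones; boundary points resolve to the higher class) and `sources`, a
#'   tibble of `id`, `distance_m` (edge distance, 0 inside) and
#'   `bearing_deg` (degrees clockwise from north toward the source
#'   centroid, in `[0, 360)`).
#' @export
query_risk <- function(map, previous, x, y, radius_m = NULL, scheme = NULL,
                       segments = 16L) {
  stopifnot(is.data.frame(map), is.finite(x), is.finite(y))
  if (nrow(map) == 0L) stop("risk map is empty", call. = FALSE)
  scheme <- scheme %||% attr(map, "scheme")
  if (is.null(radius_m)) {
    maxd <- if (inherits(scheme, "risk_scheme")) max(scheme$distances_m)
            else max(vapply(scheme, function(s) max(s$distances_m), numeric(1)))
    radius_m <- maxd + 500
  }
  stopifnot(radius_m > 0)
  disc <- disc_geom(x, y, radius_m, segments = segments)
  clipped <- list()
  for (i in seq_len(nrow(map))) {
    g <- geom_intersect(map$geometry[[i]], disc)
    if (is_empty_geom(g) || geom_area(g) <= AREA_EPS) next
    clipped[[length(clipped) + 1L]] <- tibble::tibble(
      risk_class = map$risk_class[i], band_m = map$band_m[i],
      escalated = map$escalated[i], geometry = list(g))
  }
  local_map <- if (length(clipped)) do.call(rbind, clipped) else
    map[integer(0), ]
  local_map <- new_risk_map(local_map, attr(map, "scheme"),
                            attr(map, "crs_id"), attr(map, "source_year"))
  sources <- query_sources(previous, x, y, scheme)
  structure(list(point = c(x = x, y = y), radius_m = radius_m,
                 local_map = local_map,
                 class_at_point = map_class_at(map, x, y),
                 sources = sources),
            class = "rotadist_query")
}

query_sources <- function(previous, x, y, scheme) {
  if (is.null(previous) || nrow(previous) == 0L) {
    return(tibble::tibble(id = character(0), distance_m = numeric(0),
                          bearing_deg = numeric(0)))
  }
  rows <- list()
  for (i in seq_len(nrow(previous))) {
    sch <- site_scheme(scheme, previous$crop[i] %||% "grain_pea")
    g <- previous$geometry[[i]]
    d <- dist_point_geom(x, y, g)
    if (d > max(sch$distances_m)) next
    ctr <- geom_centroid(g)
    bearing <- (atan2(ctr[1] - x, ctr[2] - y) * 180 / pi) %% 360
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = previous$id[i], distance_m = d, bearing_deg = bearing)
  }
  if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(id = character(0), distance_m = numeric(0),
                   bearing_deg = numeric(0))
}

#' @export
print.rotadist_query <- function(x, ...) {
  cat("<rotadist_query> at (", format(x$point[1]), ", ", format(x$point[2]),
      "), radius ", x$radius_m, " m\n", sep = "")
  cat("  class at point: ",
      if (is.na(x$class_at_point)) "none (outside all risk zones)"
      else x$class_at_point, "\n", sep = "")
  cat("  risk sources reaching the point: ", nrow(x$sources), "\n", sep = "")
  invisible(x)
}

#' Serialize a query result to a JSON summary
#'
#' @param q A `rotadist_query`.
#' @param path Optional output path.
#' @return JSON string, or the path invisibly when written.
#' @export
query_json <- function(q, path = NULL) {
  payload <- list(
    point = as.list(q$point), radius_m = q$radius_m,
    class_at_point = if (is.na(q$class_at_point)) NULL else q$class_at_point,
    n_zones_in_window = nrow(q$local_map),
    sources = lapply(seq_len(nrow(q$sources)), function(i)
      list(id = q$sources$id[i], distance_m = q$sources$distance_m[i],
           bearing_deg = q$sources$bearing_deg[i]))
  )
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
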