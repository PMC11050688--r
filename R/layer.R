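# Field-site layers.
#
# A layer is a tibble with one row per field site and a `geometry` list
# column of polygon geometries (see R/geom.R), carrying the attribute
# `crs_id`. All coordinates must be planar meters: every buffering and
# distance operation in this package is metric.

FIELD_CROPS <- c("grain_pea", "green_pea", "other")

#' Create a field-site layer
#'
#' @param geometry List of polygon geometries (lists of rings, planar meters).
#' @param id Character feature identifiers (default `"F001"`, ...).
#' @param year Integer 4-digit calendar year of cultivation.
#' @param crop Crop label per feature: `"grain_pea"`, `"green_pea"` or
#'   `"other"`.
#' @param insecticide Optional logical: was the site insecticide-treated?
#' @param infestation_pct Optional observed percent seed infestation in
#'   `[0, 100]`.
#' @param crs_id Coordinate reference system identifier (informational, e.g.
#'   `"EPSG:25832"`); units must be meters.
#' @return A `rotadist_layer` tibble.
#' @export
new_layer <- function(geometry, id = NULL, year = NA_integer_,
                      crop = "grain_pea", insecticide = NA,
                      infestation_pct = NA_real_, crs_id = "local-m") {
  n <- length(geometry)
  if (is.null(id)) id <- sprintf("F%03d", seq_len(n))
  out <- tibble::tibble(
    id = as.character(id),
    year = as.integer(rep_len(year, n)),
    crop = as.character(rep_len(crop, n)),
    insecticide = as.logical(rep_len(insecticide, n)),
    infestation_pct = as.numeric(rep_len(infestation_pct, n)),
    geometry = geometry
  )
  as_layer(out, crs_id = crs_id)
}

as_layer <- function(df, crs_id = "local-m") {
  stopifnot(is.data.frame(df), "geometry" %in% names(df))
  out <- tibble::as_tibble(df)
  attr(out, "crs_id") <- crs_id
  class(out) <- c("rotadist_layer", class(tibble::tibble()))
  validate_layer(out)
}

#' Coordinate reference system identifier of a layer
#' @param layer A `rotadist_layer`.
#' @return Character scalar.
#' @export
layer_crs <- function(layer) attr(layer, "crs_id")

# CRS identifiers known to be geographic (degree units); buffering in such a
# system is meaningless, so these are rejected at the door.
GEOGRAPHIC_CRS <- c("EPSG:4326", "EPSG:4258", "EPSG:4269", "EPSG:4267",
                    "OGC:CRS84", "CRS84", "WGS84")

is_geographic_crs <- function(crs_id) {
  !is.null(crs_id) && toupper(trimws(crs_id)) %in% toupper(GEOGRAPHIC_CRS)
}

#' Validate a field-site layer
#'
#' Checks per-feature invariants: valid positive-area geometry, 4-digit year
#' (when present), infestation percentage in `[0, 100]`, and a meter-unit
#' (non-geographic) CRS.
#'
#' @param layer A `rotadist_layer`.
#' @return The layer, invisibly unchanged, or an error naming the offending
#'   feature id.
#' @export
validate_layer <- function(layer) {
  if (is_geographic_crs(layer_crs(layer))) {
    stop("layer CRS '", layer_crs(layer), "' is geographic (degree units); ",
         "a projected meter-unit CRS is required. ",
         "Use reproject_lonlat_layer() to obtain planar meters.", call. = FALSE)
  }
  if (anyDuplicated(layer$id)) {
    stop("duplicate feature ids: ",
         paste(unique(layer$id[duplicated(layer$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(layer))) {
    g <- layer$geometry[[i]]
    if (!geom_is_valid(g)) {
      stop("feature '", layer$id[i], "': invalid or zero-area geometry",
           call. = FALSE)
    }
    yr <- layer$year[i]
    if (!is.na(yr) && (yr < 1000L || yr > 9999L)) {
      stop("feature '", layer$id[i], "': year must be a 4-digit integer",
           call. = FALSE)
    }
    ip <- layer$infestation_pct[i]
    if (!is.na(ip) && (ip < 0 || ip > 100)) {
      stop("feature '", layer$id[i], "': infestation_pct must lie in [0, 100]",
           call. = FALSE)
    }
  }
  invisible(layer)
}

#' @export
print.rotadist_layer <- function(x, ...) {
  cat("<rotadist_layer> ", nrow(x), " field site(s), CRS: ", layer_crs(x),
      "\n", sep = "")
  areas <- vapply(x$geometry, geom_area, numeric(1))
  cat("  total area: ", format(round(sum(areas) / 1e4, 2)), " ha\n", sep = "")
  NextMethod()
}

#' Reproject longitude/latitude coordinates to local planar meters
#'
#' Azimuthal-equidistant projection about a local origin, computed from
#' geodesic distance and bearing on the WGS84 ellipsoid. Adequate for study
#' regions a few tens of kilometers across; distortion grows with distance
#' from the origin. This is the explicit escape hatch for degree-unit input:
#' the package never reprojects silently.
#'
#' @param layer A layer whose vertex coordinates are longitude/latitude
#'   degrees (construct it with `crs_id = "pending-lonlat"` to bypass the
#'   meter-unit check, or pass a plain data frame with a geometry column).
#' @param origin Numeric `c(lon, lat)` projection origin; defaults to the
#'   mean of all vertices.
#' @return A `rotadist_layer` in planar meters with `crs_id = "local-aeqd-m"`.
#' @export
reproject_lonlat_layer <- function(layer, origin = NULL) {
  allv <- do.call(rbind, lapply(layer$geometry, function(g)
    do.call(rbind, lapply(g, function(r) cbind(r$x, r$y)))))
  if (is.null(origin)) origin <- colMeans(allv)
  proj1 <- function(lon, lat) {
    p <- cbind(lon, lat)
    d <- geosphere::distGeo(origin, p)
    th <- geosphere::bearing(origin, p) * pi / 180
    list(x = d * sin(th), y = d * cos(th))
  }
  geoms <- lapply(layer$geometry, function(g) normalize_geom(lapply(g, function(r) {
    xy <- proj1(r$x, r$y)
    list(x = xy$x, y = xy$y)
  })))
  df <- as.data.frame(layer[setdiff(names(layer), "geometry")])
  df$geometry <- geoms
  as_layer(df, crs_id = "local-aeqd-m")
}
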