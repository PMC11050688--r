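# Reading and writing polygon layers.
#
# Two dialects are supported: GeoJSON (RFC 7946 geometry encoding, written
# via jsonlite) and ESRI Shapefile (polygon geometry in R/shapefile.R, the
# .dbf attribute table through foreign). The fixed attribute schema is
#   id, year, crop, insecticide, infestation_pct        (field-site layers)
#   risk_class, band_m, escalated, source               (risk maps)
# Unknown attributes pass through untouched. Shapefile 10-character field
# names use the mapping table DBF_NAME_MAP below.

guess_format <- function(path, format = c("auto", "geojson", "shapefile")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) return("geojson")
  if (ext %in% c("shp")) return("shapefile")
  stop("cannot infer format from extension '", ext,
       "'; pass format = 'geojson' or 'shapefile'", call. = FALSE)
}

#' Read a polygon layer
#'
#' Reads field-site or risk-map polygons from GeoJSON or ESRI Shapefile.
#' Self-intersecting geometries are repaired by the standard even-odd
#' resolution (the zero-distance-buffer fix); features still invalid or with
#' zero area after repair are rejected with their id in the error message.
#' A declared geographic (degree-unit) CRS is an error: all operations in
#' this package buffer and measure in meters. Files with no declared CRS are
#' assumed to be in planar meters.
#'
#' @param path Input file path (`.geojson`/`.json` or `.shp`).
#' @param format `"auto"` (from the extension), `"geojson"` or `"shapefile"`.
#' @param crs_id Optional CRS identifier overriding the file's declaration.
#' @return A `rotadist_layer` tibble with a `geometry` list column.
#' @export
read_layer <- function(path, format = c("auto", "geojson", "shapefile"),
                       crs_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- guess_format(path, format)
  raw <- if (format == "geojson") read_geojson(path) else read_shapefile(path)
  crs <- crs_id %||% raw$crs_id %||% "unknown-assumed-m"
  if (is_geographic_crs(crs)) {
    stop("input CRS '", crs, "' uses degree units; a projected meter-unit ",
         "CRS is required (reproject_lonlat_layer() converts lon/lat input)",
         call. = FALSE)
  }
  df <- raw$df
  geoms <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    g0 <- df$geometry[[i]]
    g <- repair_geom(g0)
    fid <- if ("id" %in% names(df)) df$id[i] else as.character(i)
    if (is.null(g) || !geom_is_valid(g)) {
      stop("feature '", fid, "': geometry invalid or zero-area after repair",
           call. = FALSE)
    }
    # resolving self-intersections always restructures the rings; when the
    # structure is unchanged, keep the original coordinates (the repair's
    # grid snapping would otherwise perturb round-tripped areas)
    structurally_same <- length(g) == length(g0) &&
      sum(lengths(lapply(g, `[[`, "x"))) == sum(lengths(lapply(g0, `[[`, "x")))
    geoms[[i]] <- normalize_geom(if (structurally_same) g0 else g)
  }
  df$geometry <- geoms
  for (col in intersect(c("risk_class", "band_m", "infestation_pct"),
                        names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!"id" %in% names(df)) df$id <- sprintf("F%03d", seq_len(nrow(df)))
  for (col in c("year", "crop", "insecticide", "infestation_pct")) {
    if (!col %in% names(df)) {
      df[[col]] <- switch(col, year = NA_integer_, crop = NA_character_,
                          insecticide = NA, infestation_pct = NA_real_)
    }
  }
  front <- c("id", "year", "crop", "insecticide", "infestation_pct")
  df <- df[c(front, setdiff(names(df), c(front, "geometry")), "geometry")]
  as_layer(df, crs_id = crs)
}

#' Write a polygon layer or risk map
#'
#' @param x A `rotadist_layer` or `rotadist_risk_map`.
#' @param path Output path (`.geojson`/`.json` or `.shp`).
#' @param format `"auto"`, `"geojson"` or `"shapefile"`.
#' @return The path, invisibly.
#' @export
write_layer <- function(x, path, format = c("auto", "geojson", "shapefile")) {
  stopifnot(is.data.frame(x), nrow(x) > 0L, "geometry" %in% names(x))
  format <- guess_format(path, format)
  crs <- attr(x, "crs_id") %||% "unknown-assumed-m"
  df <- as.data.frame(x[setdiff(names(x), "geometry")])
  geoms <- lapply(x$geometry, normalize_geom)
  if (format == "geojson") {
    write_geojson(df, geoms, crs, path)
  } else {
    write_shapefile(df, geoms, crs, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- GeoJSON ----------------------------------------------------------------

# Group a flat ring list into GeoJSON polygons: each counter-clockwise ring
# is an exterior; each clockwise ring is attached to the exterior containing
# its first vertex.
rings_to_polys <- function(geom) {
  outer <- which(vapply(geom, ring_signed_area, numeric(1)) > 0)
  if (length(outer) == 0L) outer <- seq_along(geom)  # degenerate; keep all
  polys <- lapply(outer, function(i) list(geom[[i]]))
  holes <- setdiff(seq_along(geom), outer)
  for (h in holes) {
    px <- geom[[h]]$x[1]; py <- geom[[h]]$y[1]
    hit <- 1L
    for (k in seq_along(outer)) {
      if (sp::point.in.polygon(px, py, geom[[outer[k]]]$x,
                               geom[[outer[k]]]$y) >= 1L) { hit <- k; break }
    }
    polys[[hit]] <- c(polys[[hit]], list(geom[[h]]))
  }
  polys
}

ring_coords_closed <- function(ring) {
  n <- length(ring$x)
  lapply(c(seq_len(n), 1L), function(i) c(ring$x[i], ring$y[i]))
}

geom_to_geojson <- function(geom) {
  polys <- rings_to_polys(geom)
  coords <- lapply(polys, function(p) lapply(p, ring_coords_closed))
  if (length(polys) == 1L) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
}

write_geojson <- function(df, geoms, crs, path) {
  feats <- lapply(seq_along(geoms), function(i) {
    props <- lapply(df[i, , drop = FALSE], function(v) {
      v <- v[[1]]
      if (length(v) == 1L && is.na(v)) NULL else v
    })
    list(type = "Feature", properties = props,
         geometry = geom_to_geojson(geoms[[i]]))
  })
  fc <- list(type = "FeatureCollection", crs_id = crs, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
}

geojson_ring <- function(coords) {
  x <- vapply(coords, function(p) as.numeric(p[[1]]), numeric(1))
  y <- vapply(coords, function(p) as.numeric(p[[2]]), numeric(1))
  n <- length(x)
  if (n > 1L && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  list(x = x, y = y)
}

geojson_to_geom <- function(g) {
  if (g$type == "Polygon") {
    lapply(g$coordinates, geojson_ring)
  } else if (g$type == "MultiPolygon") {
    unlist(lapply(g$coordinates, function(p) lapply(p, geojson_ring)),
           recursive = FALSE)
  } else {
    stop("unsupported GeoJSON geometry type: ", g$type, call. = FALSE)
  }
}

read_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  crs_id <- fc$crs_id
  if (is.null(crs_id) && !is.null(fc$crs$properties$name)) {
    nm <- fc$crs$properties$name
    crs_id <- sub("^urn:ogc:def:crs:EPSG::", "EPSG:", nm)
  }
  feats <- fc$features
  geoms <- lapply(feats, function(f) geojson_to_geom(f$geometry))
  keys <- unique(unlist(lapply(feats, function(f) names(f$properties))))
  df <- data.frame(row.names = seq_along(feats))
  for (k in keys) {
    vals <- lapply(feats, function(f) f$properties[[k]])
    vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
    df[[k]] <- unlist(vals)
  }
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  if ("insecticide" %in% names(df)) df$insecticide <- as.logical(df$insecticide)
  if ("escalated" %in% names(df)) df$escalated <- as.logical(df$escalated)
  df$geometry <- geoms
  list(df = df, crs_id = crs_id)
}
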