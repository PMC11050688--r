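# Risk-map construction: ring buffers around previous-year crop sites,
# classed by band, then overlaid into a flat (pairwise-disjoint) map in
# which regions reached from two or more distinct sources are escalated one
# step up the class ladder — infestation pressure arriving from several
# directions is worse than the nearest source alone suggests.

# Area below which an overlay fragment is considered numerical noise.
AREA_EPS <- 1e-6

#' Minimum rotation distance from a site to a previous-year layer
#'
#' Edge-to-edge Euclidean distance from a field-site polygon to the nearest
#' polygon of the previous-year layer; 0 when geometries touch or overlap.
#' Only the nearest previous site matters for the decay model.
#'
#' @param site A polygon geometry, or a one-row `rotadist_layer`.
#' @param previous A non-empty `rotadist_layer` in the same CRS.
#' @return Distance in meters.
#' @export
nearest_distance <- function(site, previous) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L)
    site <- site$geometry[[1]]
  }
  if (!is.data.frame(previous) || nrow(previous) == 0L) {
    stop("previous-year layer is empty", call. = FALSE)
  }
  min(vapply(previous$geometry, function(g) dist_geom_geom(site, g),
             numeric(1)))
}

#' Minimum rotation distances for every site of a layer
#'
#' @param current Layer of current-year sites.
#' @param previous Layer of previous-year sites.
#' @return Numeric vector of distances in meters, one per current site.
#' @export
min_rotation_distances <- function(current, previous) {
  vapply(seq_len(nrow(current)),
         function(i) nearest_distance(current[i, ], previous), numeric(1))
}

site_scheme <- function(schemes, crop) {
  if (inherits(schemes, "risk_scheme")) return(schemes)
  s <- schemes[[crop]]
  if (is.null(s)) stop("no risk scheme configured for crop '", crop, "'",
                       call. = FALSE)
  s
}

#' Build per-source ring buffers
#'
#' For every previous-year site and every band of its scheme, constructs the
#' ring between consecutive buffer distances. The innermost zone is the full
#' buffer at the first distance and includes the source polygon itself (an
#' unrotated field is the maximal-risk case). Rings of one source are
#' disjoint by construction; rings of different sources may overlap and are
#' resolved by [flatten_with_escalation()].
#'
#' @param previous `rotadist_layer` of previous-year crop sites.
#' @param scheme A single `risk_scheme`, or a named list of schemes keyed by
#'   crop label for mixed landscapes.
#' @param segments Buffer arc segments per quarter circle (default 16).
#' @return A `risk_zones` tibble: `source`, `band_m`, `risk_class`,
#'   `escalated` (all `FALSE`), `geometry`.
#' @export
build_buffers <- function(previous, scheme, segments = 16L) {
  stopifnot(is.data.frame(previous), nrow(previous) > 0L)
  rows <- list()
  for (i in seq_len(nrow(previous))) {
    sch <- site_scheme(scheme, previous$crop[i] %||% "grain_pea")
    g <- previous$geometry[[i]]
    prev_buf <- NULL
    for (k in seq_along(sch$distances_m)) {
      buf <- buffer_geom(g, sch$distances_m[k], segments = segments)
      zone <- if (k == 1L) buf else geom_minus(buf, prev_buf)
      prev_buf <- buf
      if (is_empty_geom(zone)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        source = previous$id[i], band_m = sch$distances_m[k],
        risk_class = sch$classes[k], escalated = FALSE,
        geometry = list(zone))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "crs_id") <- attr(previous, "crs_id") %||% "local-m"
  class(out) <- c("rotadist_risk_zones", class(tibble::tibble()))
  out
}

new_risk_map <- function(zones, scheme, crs_id, source_year = NA_integer_) {
  attr(zones, "scheme") <- scheme
  attr(zones, "crs_id") <- crs_id
  attr(zones, "source_year") <- source_year
  class(zones) <- c("rotadist_risk_map", class(tibble::tibble()))
  zones
}

#' @export
print.rotadist_risk_map <- function(x, ...) {
  cat("<rotadist_risk_map> ", nrow(x), " zone(s), classes ",
      paste(sort(unique(x$risk_class)), collapse = "/"),
      ", CRS: ", attr(x, "crs_id"), "\n", sep = "")
  NextMethod()
}

# Union of all zones belonging to one source id.
source_footprints <- function(zones) {
  lapply(split(seq_len(nrow(zones)), zones$source),
         function(idx) geom_union(zones$geometry[idx]))
}

# Cumulative coverage unions: element k is the region covered by at least k
# distinct source footprints. Empty regions are list() sentinels (assigning
# NULL would delete the list element).
coverage_depth_unions <- function(footprints, max_depth) {
  u <- rep(list(list()), max_depth)
  for (f in footprints) {
    for (k in rev(seq_len(max_depth - 1L))) {
      if (!is_empty_geom(u[[k]])) {
        deeper <- geom_union2(u[[k + 1L]], geom_intersect(u[[k]], f))
        u[k + 1L] <- list(deeper %||% list())
      }
    }
    u[1L] <- list(geom_union2(u[[1L]], f) %||% list())
  }
  u
}

#' Flatten overlapping risk zones with class escalation
#'
#' Overlays per-source ring buffers into a flat risk map: zone interiors are
#' pairwise disjoint and their union equals the union of the input buffers.
#' Each region keeps the maximum class among the zones covering it; regions
#' covered by two or more distinct sources are escalated up the scheme
#' ladder (one step by default, or `k - 1` steps for `k` covering sources in
#' `"per-source-step"` mode), saturating at the ladder cap. Where zones of
#' unequal class overlap, escalation starts from the higher class: risk is
#' at least that of the worse source.
#'
#' @param zones Output of [build_buffers()].
#' @param scheme The `risk_scheme` supplying the ladder and escalation mode.
#' @param source_year Optional year attribute recorded on the map.
#' @return A `rotadist_risk_map` tibble: `risk_class`, `band_m`,
#'   `escalated`, `geometry`.
#' @export
flatten_with_escalation <- function(zones, scheme, source_year = NA_integer_) {
  stopifnot(is.data.frame(zones), nrow(zones) > 0L)
  crs <- attr(zones, "crs_id") %||% "local-m"
  fps <- source_footprints(zones)
  n_src <- length(fps)
  max_depth <- if (scheme$escalation == "per-source-step") max(n_src, 2L) else 2L
  cov <- coverage_depth_unions(fps, max_depth)

  # priority overlay: higher class wins; ties broken toward the inner band
  grp_key <- paste(zones$risk_class, zones$band_m)
  grps <- unique(data.frame(risk_class = zones$risk_class,
                            band_m = zones$band_m))
  grps <- grps[order(-grps$risk_class, grps$band_m), , drop = FALSE]
  taken <- NULL
  pieces <- list()
  add_piece <- function(g, class, band, escalated) {
    if (is_empty_geom(g) || geom_area(g) <= AREA_EPS) return()
    pieces[[length(pieces) + 1L]] <<- tibble::tibble(
      risk_class = class, band_m = band, escalated = escalated,
      geometry = list(g))
  }
  for (r in seq_len(nrow(grps))) {
    idx <- which(grp_key == paste(grps$risk_class[r], grps$band_m[r]))
    ug <- geom_union(zones$geometry[idx])
    rg <- if (is_empty_geom(taken)) ug else geom_minus(ug, taken)
    taken <- if (is_empty_geom(taken)) ug else geom_union2(taken, ug)
    if (is_empty_geom(rg)) next
    cls <- grps$risk_class[r]; band <- grps$band_m[r]
    if (scheme$escalation == "per-source-step") {
      for (k in seq_len(max_depth)) {
        exact <- if (k < max_depth && !is_empty_geom(cov[[k + 1L]]))
          geom_minus(cov[[k]], cov[[k + 1L]]) else cov[[k]]
        if (is_empty_geom(exact)) next
        part <- geom_intersect(rg, exact)
        if (k == 1L) add_piece(part, cls, band, FALSE)
        else add_piece(part, next_class(scheme, cls, steps = k - 1L), band, TRUE)
      }
    } else {
      multi <- cov[[2L]]
      if (is_empty_geom(multi)) {
        add_piece(rg, cls, band, FALSE)
      } else {
        add_piece(geom_minus(rg, multi), cls, band, FALSE)
        add_piece(geom_intersect(rg, multi), next_class(scheme, cls), band, TRUE)
      }
    }
  }
  out <- do.call(rbind, pieces)
  # merge fragments that ended up with identical class/band/escalation
  key <- paste(out$risk_class, out$band_m, out$escalated)
  merged <- lapply(split(seq_len(nrow(out)), key), function(idx) {
    tibble::tibble(risk_class = out$risk_class[idx[1]],
                   band_m = out$band_m[idx[1]],
                   escalated = out$escalated[idx[1]],
                   geometry = list(geom_union(out$geometry[idx])))
  })
  merged <- do.call(rbind, merged)
  merged <- merged[order(-merged$risk_class, merged$band_m, merged$escalated), ]
  new_risk_map(merged, scheme, crs, source_year)
}

#' Build a flat risk map from a previous-year layer
#'
#' Convenience wrapper: [build_buffers()] then [flatten_with_escalation()].
#'
#' @inheritParams build_buffers
#' @param ladder_scheme Scheme providing the escalation ladder when `scheme`
#'   is a per-crop list; defaults to the first element.
#' @param source_year Year recorded on the map (default: the layer's
#'   `year`).
#' @return A `rotadist_risk_map`.
#' @export
build_risk_map <- function(previous, scheme, segments = 16L,
                           ladder_scheme = NULL,
                           source_year = NA_integer_) {
  zones <- build_buffers(previous, scheme, segments = segments)
  lsch <- ladder_scheme %||%
    (if (inherits(scheme, "risk_scheme")) scheme else scheme[[1]])
  if (is.na(source_year) && !all(is.na(previous$year))) {
    source_year <- max(previous$year, na.rm = TRUE)
  }
  flatten_with_escalation(zones, lsch, source_year = source_year)
}

#' Risk class of the flattened map at query points
#'
#' @param map A `rotadist_risk_map`.
#' @param px,py Point coordinate vectors (meters).
#' @return Numeric vector of classes; `NA` outside all zones. Points on a
#'   zone boundary take the highest class among adjacent zones.
#' @export
map_class_at <- function(map, px, py) {
  out <- rep(NA_real_, length(px))
  ord <- order(-map$risk_class)
  for (i in ord) {
    hit <- is.na(out) & point_in_geom(px, py, map$geometry[[i]])
    out[hit] <- map$risk_class[i]
  }
  out
}
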