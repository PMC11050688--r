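# Synthetic landscape generator.
#
# Emulates the study's input data so every module is testable without
# external downloads: irregular convex field parcels of 1-50 ha scattered
# without overlap in a circular region ~30 km across (the approximate
# diameter of each monitored growing region), plus distance-infestation
# observations drawn from the decay curve with additive truncated Gaussian
# noise at the reported residual scale. All randomness is derived from the
# spec seed; repeated calls are bit-identical.

#' Specify a synthetic landscape
#'
#' @param n_fields Number of field parcels per year (>= 1).
#' @param region_diameter_m Diameter of the circular study region (default
#'   30,000 m).
#' @param area_range_ha Field-size range in hectares (default 1-50).
#' @param years Calendar years to generate (each year gets an independent
#'   draw, so some fields land near previous-year fields by chance).
#' @param seed Integer seed fixing all randomness.
#' @param decay_a,decay_b Decay-curve parameters for observation generation
#'   (defaults: the published all-grain-pea estimates 9.79 % and 1260.7 m).
#' @param noise_sd Additive Gaussian noise SD in percent (default 9.1, the
#'   published residual scale).
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(n_fields = 25L, region_diameter_m = 30000,
                           area_range_ha = c(1, 50),
                           years = c(2015L, 2016L), seed = 1L,
                           decay_a = 9.79, decay_b = 1260.7, noise_sd = 9.1) {
  stopifnot(n_fields >= 1L, region_diameter_m > 0,
            length(area_range_ha) == 2L, all(area_range_ha > 0),
            area_range_ha[1] <= area_range_ha[2],
            decay_a > 0, decay_b > 0, noise_sd >= 0)
  structure(list(n_fields = as.integer(n_fields),
                 region_diameter_m = region_diameter_m,
                 area_range_ha = area_range_ha,
                 years = as.integer(years), seed = as.integer(seed),
                 decay_a = decay_a, decay_b = decay_b, noise_sd = noise_sd),
            class = "landscape_spec")
}

# Deterministic sub-seed, kept well below 2^31.
derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) %% 2039999) * 1000 + salt %% 1000)
}

# One random convex quadrilateral-ish parcel of exactly `area_m2`, centered
# at (cx, cy): a rotated rectangle with perturbed corners, convex-hulled,
# then rescaled about its centroid to the target area.
random_parcel <- function(cx, cy, area_m2) {
  aspect <- stats::runif(1, 1, 3)
  w <- sqrt(area_m2 * aspect); h <- area_m2 / w
  corners <- rbind(c(-w, -h), c(w, -h), c(w, h), c(-w, h)) / 2
  corners <- corners * (1 + matrix(stats::runif(8, -0.15, 0.15), 4, 2))
  th <- stats::runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- corners %*% rot
  hull <- grDevices::chull(pts)
  ring <- list(x = pts[hull, 1], y = pts[hull, 2])
  if (ring_signed_area(ring) < 0) ring <- list(x = rev(ring$x), y = rev(ring$y))
  g <- list(ring)
  s <- sqrt(area_m2 / geom_area(g))   # exact target area
  ctr <- geom_centroid(g)
  g <- list(list(x = (ring$x - ctr[1]) * s + cx,
                 y = (ring$y - ctr[2]) * s + cy))
  g
}

#' Generate one year of non-overlapping synthetic field parcels
#'
#' Rejection-samples parcel placements until `n_fields` mutually
#' non-overlapping parcels fit in the region, erroring after a documented
#' retry cap of `200 * n_fields` draws.
#'
#' @param spec A `landscape_spec`.
#' @param year Year label (must be one of `spec$years`); the per-year seed
#'   is derived from `spec$seed` and the year, so years are independent but
#'   reproducible.
#' @param crop Crop label(s) for the parcels (recycled).
#' @return A `rotadist_layer` of `spec$n_fields` field sites.
#' @export
generate_fields <- function(spec, year = spec$years[1], crop = "grain_pea") {
  stopifnot(inherits(spec, "landscape_spec"))
  R <- spec$region_diameter_m / 2
  withr::with_seed(derive_seed(spec$seed, year), {
    geoms <- list(); bbs <- list()
    tries <- 0L; cap <- 200L * spec$n_fields
    while (length(geoms) < spec$n_fields) {
      tries <- tries + 1L
      if (tries > cap) {
        stop("infeasible packing: could not place ", spec$n_fields,
             " non-overlapping fields after ", cap, " draws", call. = FALSE)
      }
      area <- stats::runif(1, spec$area_range_ha[1], spec$area_range_ha[2]) * 1e4
      rad <- sqrt(stats::runif(1)) * max(R - sqrt(area), 0)
      ang <- stats::runif(1, 0, 2 * pi)
      g <- random_parcel(rad * cos(ang), rad * sin(ang), area)
      bb <- geom_bbox(g)
      clash <- FALSE
      for (j in seq_along(geoms)) {
        ob <- bbs[[j]]
        if (bb["xmin"] > ob["xmax"] || bb["xmax"] < ob["xmin"] ||
            bb["ymin"] > ob["ymax"] || bb["ymax"] < ob["ymin"]) next
        if (!is_empty_geom(geom_intersect(g, geoms[[j]]))) { clash <- TRUE; break }
      }
      if (clash) next
      geoms[[length(geoms) + 1L]] <- g
      bbs[[length(bbs) + 1L]] <- bb
    }
    new_layer(geoms,
              id = sprintf("Y%d_F%03d", year, seq_along(geoms)),
              year = year, crop = crop,
              insecticide = stats::runif(spec$n_fields) < 0.5,
              crs_id = "local-m")
  })
}

#' Generate distance-infestation observations from a field pair of years
#'
#' For each current-year field, computes the minimum edge-to-edge distance
#' to the previous-year layer and draws an observed infestation
#' `max(0, min(100, a * exp(-md/b) + N(0, noise_sd)))`.
#'
#' @param current Current-year `rotadist_layer`.
#' @param previous Previous-year `rotadist_layer`.
#' @param spec A `landscape_spec` (decay parameters, noise SD, seed).
#' @return Tibble with `site_id`, `md_m`, `infestation_pct`, `insecticide`.
#' @export
generate_observations <- function(current, previous, spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (is.null(previous) || nrow(previous) == 0L) {
    stop("previous-year layer is empty", call. = FALSE)
  }
  md <- min_rotation_distances(current, previous)
  withr::with_seed(derive_seed(spec$seed, 777L), {
    noise <- if (spec$noise_sd > 0) stats::rnorm(length(md), 0, spec$noise_sd)
             else 0
    y <- pmin(100, pmax(0, spec$decay_a * exp(-md / spec$decay_b) + noise))
    tibble::tibble(site_id = current$id, md_m = md, infestation_pct = y,
                   insecticide = current$insecticide)
  })
}
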