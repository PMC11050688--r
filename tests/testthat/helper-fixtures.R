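# Shared fixtures and independent oracles for the test suite.
#
# The oracles deliberately avoid the package's polygon-overlay code paths:
# distances are computed point-by-point against raw polygon boundaries, and
# risk classes by per-source distance banding plus the escalation rule.

square_geom <- function(x0, y0, side = 100) {
  rect_geom(x0, y0, x0 + side, y0 + side)
}

# Layer of axis-aligned squares given lower-left corners.
square_layer <- function(xs, ys, side = 100, year = 2015, crop = "grain_pea",
                         insecticide = NA) {
  new_layer(mapply(square_geom, xs, ys, MoreArgs = list(side = side),
                   SIMPLIFY = FALSE),
            year = year, crop = crop, insecticide = insecticide)
}

# Random convex polygon with vertices on a jittered circle.
random_convex_poly <- function(cx, cy, r = 5) {
  n <- sample(4:8, 1)
  th <- sort(stats::runif(n, 0, 2 * pi))
  rad <- r * stats::runif(n, 0.6, 1)
  pts <- cbind(cx + rad * cos(th), cy + rad * sin(th))
  hull <- grDevices::chull(pts)
  list(list(x = pts[hull, 1], y = pts[hull, 2]))
}

# --- independent distance oracle -------------------------------------------

oracle_pt_seg <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 == 0, 0, ((px - x1) * dx + (py - y1) * dy) / len2)
  t <- pmin(1, pmax(0, t))
  sqrt((x1 + t * dx - px)^2 + (y1 + t * dy - py)^2)
}

oracle_dist_point_poly <- function(px, py, geom) {
  inside <- 0L
  for (ring in geom) {
    code <- sp::point.in.polygon(px, py, ring$x, ring$y)
    if (code >= 2L) return(0)
    inside <- inside + (code == 1L)
  }
  if (inside %% 2L == 1L) return(0)
  d <- Inf
  for (ring in geom) {
    d <- min(d, oracle_pt_seg(px, py, ring$x, ring$y,
                              c(ring$x[-1], ring$x[1]),
                              c(ring$y[-1], ring$y[1])))
  }
  d
}

# Densified boundary point cloud (for the vertex-sampling distance oracle).
oracle_boundary_points <- function(geom, step = 0.1) {
  pts <- NULL
  for (ring in geom) {
    x2 <- c(ring$x[-1], ring$x[1]); y2 <- c(ring$y[-1], ring$y[1])
    for (k in seq_along(ring$x)) {
      len <- sqrt((x2[k] - ring$x[k])^2 + (y2[k] - ring$y[k])^2)
      m <- max(2L, ceiling(len / step))
      t <- seq(0, 1, length.out = m)
      pts <- rbind(pts, cbind(ring$x[k] + t * (x2[k] - ring$x[k]),
                              ring$y[k] + t * (y2[k] - ring$y[k])))
    }
  }
  pts
}

# --- pointwise risk-class oracle -------------------------------------------

# Class at one point by per-source exact distance banding + escalation;
# returns NA outside all bands. `schemes` is a risk_scheme or per-crop list.
oracle_class_at <- function(px, py, previous, schemes, ladder_scheme = NULL) {
  get_scheme <- function(crop) {
    if (inherits(schemes, "risk_scheme")) schemes else schemes[[crop]]
  }
  lsch <- ladder_scheme %||%
    (if (inherits(schemes, "risk_scheme")) schemes else schemes[[1]])
  classes <- c()
  for (i in seq_len(nrow(previous))) {
    sch <- get_scheme(previous$crop[i])
    d <- oracle_dist_point_poly(px, py, previous$geometry[[i]])
    k <- which(d <= sch$distances_m)[1]
    if (!is.na(k)) classes <- c(classes, sch$classes[k])
  }
  if (length(classes) == 0L) return(NA_real_)
  mx <- max(classes)
  if (length(classes) >= 2L) {
    steps <- if (lsch$escalation == "per-source-step") length(classes) - 1L
             else 1L
    i <- match(mx, lsch$ladder)
    lsch$ladder[min(i + steps, length(lsch$ladder))]
  } else {
    mx
  }
}

# TRUE when the point's exact distance to some source sits within `tol`
# meters of one of that source's band edges (where the polygonal arc
# approximation of the buffer makes the band assignment ambiguous).
oracle_near_band_edge <- function(px, py, previous, schemes, tol = 5) {
  for (i in seq_len(nrow(previous))) {
    sch <- if (inherits(schemes, "risk_scheme")) schemes
           else schemes[[previous$crop[i]]]
    d <- oracle_dist_point_poly(px, py, previous$geometry[[i]])
    if (any(abs(d - sch$distances_m) <= tol)) return(TRUE)
  }
  FALSE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

map_area <- function(geoms) sum(vapply(geoms, geom_area, numeric(1)))
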