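# Ring buffers, overlap escalation, and flat-map invariants.

test_that("nearest rotation distance is edge-to-edge against the closest site", {
  prev <- square_layer(c(0, 1000), c(0, 0), side = 100, year = 2015)
  cur <- square_layer(300, 0, side = 100, year = 2016)
  expect_equal(nearest_distance(cur[1, ], prev), 200)   # nearer of 200 / 600
  touching <- square_layer(100, 0, side = 100, year = 2016)
  expect_equal(nearest_distance(touching[1, ], prev), 0)
  expect_error(nearest_distance(cur[1, ], prev[integer(0), ]), "empty")
  expect_equal(min_rotation_distances(cur, prev), 200)
})

test_that("ring buffers nest: band areas add up to the full buffer", {
  prev <- square_layer(0, 0, side = 300, year = 2015)
  sch <- grain_pea_scheme()
  zones <- build_buffers(prev, sch)
  expect_equal(nrow(zones), 3L)
  expect_equal(zones$risk_class, c(4, 2, 1))
  expect_equal(zones$band_m, c(1261, 1560, 1825))
  g <- prev$geometry[[1]]
  a1 <- geom_area(buffer_geom(g, 1261))
  a2 <- geom_area(buffer_geom(g, 1560))
  a3 <- geom_area(buffer_geom(g, 1825))
  expect_equal(geom_area(zones$geometry[[1]]), a1, tolerance = 1e-9)
  expect_equal(geom_area(zones$geometry[[2]]), a2 - a1, tolerance = 1e-9)
  expect_equal(geom_area(zones$geometry[[3]]), a3 - a2, tolerance = 1e-9)
  # the innermost zone contains the source field itself
  expect_true(point_in_geom(150, 150, zones$geometry[[1]]))
})

test_that("single-band buffer around a circular field matches the annulus", {
  g <- disc_geom(0, 0, 200, segments = 32)
  l <- new_layer(list(g), year = 2015)
  zones <- build_buffers(l, risk_scheme(500, 2), segments = 32)
  # vertices lie on the true circles; area is bounded by the inscribed
  # polygon below and pi (r+d)^2 above
  expect_lt(geom_area(zones$geometry[[1]]), pi * 700^2)
  expect_gt(geom_area(zones$geometry[[1]]), pi * 700^2 * 0.999)
})

test_that("identical far-apart fields get identical per-band areas", {
  prev <- square_layer(c(0, 50000), c(0, 0), side = 250, year = 2015)
  zones <- build_buffers(prev, grain_pea_scheme())
  a <- vapply(zones$geometry, geom_area, numeric(1))
  expect_equal(a[1:3], a[4:6], tolerance = 1e-9)
})

test_that("two overlapping equal-class buffers escalate one exponential step", {
  # two fields 1500 m apart, single 1000 m band of class 2
  prev <- square_layer(c(0, 1600), c(0, 0), side = 100, year = 2015)
  sch <- risk_scheme(1000, 2, ladder = c(1, 2, 4, 8))
  m <- flatten_with_escalation(build_buffers(prev, sch), sch)
  expect_setequal(unique(m$risk_class), c(2, 4))
  # midpoint between the fields is covered by both buffers
  expect_equal(map_class_at(m, 850, 50), 4)
  # a point near one field only keeps class 2
  expect_equal(map_class_at(m, -500, 50), 2)
  expect_true(all(m$escalated[m$risk_class == 4]))
})

test_that("a single source is never escalated (identity flatten)", {
  prev <- square_layer(0, 0, side = 200, year = 2015)
  zones <- build_buffers(prev, grain_pea_scheme())
  m <- flatten_with_escalation(zones, grain_pea_scheme())
  expect_equal(sort(m$risk_class), sort(zones$risk_class))
  expect_false(any(m$escalated))
  a0 <- sort(vapply(zones$geometry, geom_area, numeric(1)))
  a1 <- sort(vapply(m$geometry, geom_area, numeric(1)))
  expect_equal(a0, a1, tolerance = 1e-9)
})

test_that("escalation saturates at the ladder cap", {
  prev <- square_layer(c(0, 150, 300), c(0, 0, 0), side = 100, year = 2015)
  sch <- risk_scheme(1000, 8, ladder = c(1, 2, 4, 8))
  m <- flatten_with_escalation(build_buffers(prev, sch), sch)
  expect_true(all(m$risk_class <= 8))
  expect_equal(map_class_at(m, 200, 50), 8)
})

test_that("unequal-class overlaps escalate from the higher covering class", {
  # field A's inner band (class 4) overlaps field B's middle band (class 2)
  prev <- square_layer(c(0, 2800), c(0, 0), side = 100, year = 2015)
  sch <- grain_pea_scheme()
  m <- flatten_with_escalation(build_buffers(prev, sch), sch)
  # point 1200 m east of A's edge: inner band of A (class 4), middle band of
  # B (edge distance 1500) -> escalate from the higher class, 4 to 8
  expect_equal(map_class_at(m, 1300, 50), 8)
})

test_that("per-source-step escalation climbs one rung per extra source", {
  prev <- square_layer(c(0, 200, 400), c(0, 0, 0), side = 100, year = 2015)
  sch <- risk_scheme(1000, 2, ladder = c(1, 2, 4, 8),
                     escalation = "per-source-step")
  m <- flatten_with_escalation(build_buffers(prev, sch), sch)
  expect_equal(map_class_at(m, 250, 50), 8)      # covered by all three
  expect_equal(map_class_at(m, -700, 50), 4)     # two sources reach here
  expect_equal(map_class_at(m, -950, 50), 2)     # only the first source
})

test_that("flattening is idempotent on its own output", {
  prev <- square_layer(c(0, 1600), c(0, 0), side = 100, year = 2015)
  sch <- risk_scheme(1000, 2, ladder = c(1, 2, 4, 8))
  m <- flatten_with_escalation(build_buffers(prev, sch), sch)
  # treat the flat map as zones from one synthetic source: nothing changes
  zones2 <- m
  zones2$source <- "all"
  m2 <- flatten_with_escalation(zones2, sch)
  expect_equal(sort(m2$risk_class), sort(m$risk_class))
  a0 <- sort(vapply(m$geometry, geom_area, numeric(1)))
  a1 <- sort(vapply(m2$geometry, geom_area, numeric(1)))
  expect_equal(a0, a1, tolerance = 1e-6)
})

test_that("flat maps are disjoint, conservative, and monotone under escalation", {
  spec <- landscape_spec(n_fields = 10, seed = 101, years = 2015L)
  prev <- generate_fields(spec, 2015)
  zones <- build_buffers(prev, grain_pea_scheme())
  m <- flatten_with_escalation(zones, grain_pea_scheme())
  # pairwise interior intersections are numerically empty
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      x <- geom_intersect(m$geometry[[i]], m$geometry[[j]])
      if (!is.null(x)) expect_lt(geom_area(x), 1e-6)
    }
  }
  # no buffered area is lost or invented
  a_in <- geom_area(geom_union(zones$geometry))
  a_out <- geom_area(geom_union(m$geometry))
  expect_lt(abs(a_in - a_out) / a_in, 1e-6)
  # every output class >= the max input class covering a probe point
  set.seed(1)
  R <- spec$region_diameter_m / 2
  px <- runif(200, -R, R); py <- runif(200, -R, R)
  out_cls <- map_class_at(m, px, py)
  for (k in seq_along(px)) {
    covering <- vapply(seq_len(nrow(zones)), function(i)
      point_in_geom(px[k], py[k], zones$geometry[[i]]), logical(1))
    if (any(covering)) {
      expect_gte(out_cls[k], max(zones$risk_class[covering]))
    } else {
      expect_true(is.na(out_cls[k]))
    }
  }
})

test_that("flat-map classes match the pointwise distance-band oracle", {
  spec <- landscape_spec(n_fields = 10, seed = 202, years = 2015L)
  prev <- generate_fields(spec, 2015)
  sch <- grain_pea_scheme()
  m <- build_risk_map(prev, sch)
  set.seed(2)
  R <- spec$region_diameter_m / 2
  px <- runif(300, -R, R); py <- runif(300, -R, R)
  keep <- !vapply(seq_along(px), function(k)
    oracle_near_band_edge(px[k], py[k], prev, sch, tol = 5), logical(1))
  got <- map_class_at(m, px[keep], py[keep])
  want <- vapply(which(keep), function(k)
    oracle_class_at(px[k], py[k], prev, sch), numeric(1))
  expect_identical(is.na(got), is.na(want))
  expect_equal(got[!is.na(got)], want[!is.na(want)])
})

test_that("mixed-crop landscapes use their per-crop schemes", {
  prev <- square_layer(c(0, 10000), c(0, 0), side = 200, year = 2015,
                       crop = c("grain_pea", "green_pea"))
  schemes <- list(grain_pea = grain_pea_scheme(), green_pea = green_pea_scheme())
  zones <- build_buffers(prev, schemes)
  expect_equal(sum(zones$source == "F001"), 3L)  # three grain bands
  expect_equal(sum(zones$source == "F002"), 1L)  # one green band
  expect_equal(zones$band_m[zones$source == "F002"], 500)
  m <- build_risk_map(prev, schemes)
  expect_equal(map_class_at(m, 10100, 400), 2)       # inside green band
  expect_true(is.na(map_class_at(m, 10100, 5000)))   # beyond 500 m of green
})
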