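# Vector I/O: GeoJSON and shapefile round-trips, CRS policy, repair policy.

make_test_layer <- function() {
  l <- square_layer(c(0, 500, 1200), c(0, 300, -400), side = 200,
                    year = 2016, crop = c("grain_pea", "green_pea", "grain_pea"),
                    insecticide = c(TRUE, FALSE, NA))
  l$infestation_pct <- c(9.5, 0.1, NA)
  l
}

test_that("GeoJSON round-trip preserves count, ids, years and areas", {
  l <- make_test_layer()
  p <- file.path(tempdir(), "l.geojson")
  write_layer(l, p)
  r <- read_layer(p)
  expect_equal(nrow(r), 3L)
  expect_equal(r$id, l$id)
  expect_equal(r$year, l$year)
  expect_equal(r$crop, l$crop)
  expect_equal(r$insecticide, l$insecticide)
  expect_equal(r$infestation_pct, l$infestation_pct)
  expect_equal(layer_crs(r), layer_crs(l))
  a0 <- vapply(l$geometry, geom_area, numeric(1))
  a1 <- vapply(r$geometry, geom_area, numeric(1))
  expect_lt(max(abs(a0 - a1)), 1e-6)
})

test_that("shapefile round-trip preserves vertex counts, areas and attributes", {
  l <- make_test_layer()
  p <- file.path(tempdir(), "l.shp")
  write_layer(l, p)
  r <- read_layer(p)
  expect_equal(nrow(r), 3L)
  expect_equal(r$id, l$id)
  expect_equal(r$year, l$year)
  expect_equal(r$insecticide, l$insecticide)
  nv0 <- vapply(l$geometry, function(g) sum(lengths(lapply(g, `[[`, "x"))),
                integer(1))
  nv1 <- vapply(r$geometry, function(g) sum(lengths(lapply(g, `[[`, "x"))),
                integer(1))
  expect_equal(nv0, nv1)
  a0 <- vapply(l$geometry, geom_area, numeric(1))
  a1 <- vapply(r$geometry, geom_area, numeric(1))
  expect_lt(max(abs(a0 - a1)), 1e-6)
})

test_that("a polygon with a hole survives both formats", {
  g <- list(rect_geom(0, 0, 100, 100)[[1]],
            list(x = rev(c(40, 60, 60, 40)), y = rev(c(40, 40, 60, 60))))
  l <- new_layer(list(g), year = 2016)
  for (ext in c("hole.geojson", "hole.shp")) {
    p <- file.path(tempdir(), ext)
    write_layer(l, p)
    r <- read_layer(p)
    expect_equal(geom_area(r$geometry[[1]]), 100 * 100 - 400, tolerance = 1e-9)
    expect_false(point_in_geom(50, 50, r$geometry[[1]]))
    expect_true(point_in_geom(10, 10, r$geometry[[1]]))
  }
})

test_that("risk-map write/read preserves risk classes exactly in both formats", {
  prev <- square_layer(c(0, 800), c(0, 0), side = 300, year = 2015)
  m <- build_risk_map(prev, grain_pea_scheme())
  for (ext in c("m.geojson", "m.shp")) {
    p <- file.path(tempdir(), ext)
    write_layer(m, p)
    r <- read_layer(p)
    expect_equal(nrow(r), nrow(m))
    expect_equal(sort(r$risk_class), sort(m$risk_class))
    expect_equal(sort(r$band_m), sort(m$band_m))
    a0 <- sort(vapply(m$geometry, geom_area, numeric(1)))
    a1 <- sort(vapply(r$geometry, geom_area, numeric(1)))
    expect_lt(max(abs(a0 - a1)), 1e-6)
  }
})

test_that("a declared geographic CRS is rejected with a meter-unit message", {
  l <- make_test_layer()
  p <- file.path(tempdir(), "geo.geojson")
  write_layer(l, p)
  txt <- readLines(p)
  writeLines(sub("local-m", "EPSG:4326", txt), p)
  expect_error(read_layer(p), "meter")
  expect_error(new_layer(list(rect_geom(0, 0, 1, 1)), crs_id = "EPSG:4326"),
               "meter")
})

test_that("missing files and unknown formats error clearly", {
  expect_error(read_layer(file.path(tempdir(), "nope.geojson")), "not found")
  p <- file.path(tempdir(), "exists.xyz")
  writeLines("{}", p)
  expect_error(read_layer(p), "format")
})

test_that("self-intersecting input is repaired, zero-area input rejected by id", {
  # bowtie ring: repairable
  fc <- list(type = "FeatureCollection", crs_id = "local-m", features = list(
    list(type = "Feature", properties = list(id = "BOW", year = 2016L),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(0, 0), c(2, 1), c(0, 1), c(2, 0), c(0, 0)))))))
  p <- file.path(tempdir(), "bow.geojson")
  jsonlite::write_json(fc, p, auto_unbox = TRUE, digits = NA)
  r <- read_layer(p)
  expect_equal(geom_area(r$geometry[[1]]), 1, tolerance = 1e-6)
  # degenerate zero-area ring: rejected, message carries the id
  fc$features[[1]]$properties$id <- "ZERO"
  fc$features[[1]]$geometry$coordinates <-
    list(list(c(0, 0), c(1, 0), c(2, 0), c(0, 0)))
  jsonlite::write_json(fc, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_layer(p), "ZERO")
})

test_that("unknown attributes pass through GeoJSON untouched", {
  l <- make_test_layer()
  l$notes <- c("a", "b", "c")
  p <- file.path(tempdir(), "extra.geojson")
  write_layer(l, p)
  r <- read_layer(p)
  expect_equal(r$notes, c("a", "b", "c"))
})

test_that("lon/lat reprojection yields meter-scale planar coordinates", {
  # ~1 km square near Quedlinburg, Germany
  lon0 <- 11.1; lat0 <- 51.8
  dlat <- 1000 / 111194.9
  dlon <- 1000 / (111194.9 * cos(lat0 * pi / 180))
  g <- list(list(x = c(lon0, lon0 + dlon, lon0 + dlon, lon0),
                 y = c(lat0, lat0, lat0 + dlat, lat0 + dlat)))
  ll <- new_layer(list(g), year = 2016, crs_id = "pending-lonlat")
  pl <- reproject_lonlat_layer(ll)
  expect_equal(layer_crs(pl), "local-aeqd-m")
  expect_equal(geom_area(pl$geometry[[1]]), 1e6, tolerance = 0.01)
})
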