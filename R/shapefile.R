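# Minimal ESRI Shapefile (polygon, shape type 5) geometry reader/writer.
#
# Only what this package needs: one .shp/.shx pair of polygon records plus a
# .dbf attribute table (delegated to foreign) and a .prj text file carrying
# the CRS identifier. Shapefile convention: exterior rings clockwise, holes
# counter-clockwise; rings are stored closed. No installed package reads
# shapefile geometry in this stack, hence the hand-written record codec.

# dBase limits field names to 10 characters; fixed mapping for the schema.
DBF_NAME_MAP <- c(
  id = "ID", year = "YEAR", crop = "CROP", insecticide = "INSECTICID",
  infestation_pct = "INFEST_PCT", risk_class = "RISK_CLASS",
  band_m = "BAND_M", escalated = "ESCALATED", source = "SOURCE"
)

to_dbf_names <- function(nms) {
  out <- ifelse(nms %in% names(DBF_NAME_MAP), DBF_NAME_MAP[nms],
                toupper(substr(nms, 1, 10)))
  make.unique(out, sep = "")
}

from_dbf_names <- function(nms) {
  rev_map <- stats::setNames(names(DBF_NAME_MAP), DBF_NAME_MAP)
  ifelse(nms %in% names(rev_map), rev_map[nms], tolower(nms))
}

# Serialize one polygon record's content (shape type 5) to a raw vector.
shp_record_content <- function(geom) {
  # shapefile orientation: exterior CW, holes CCW (mirror of our convention)
  rings <- lapply(geom, function(r) list(x = rev(r$x), y = rev(r$y)))
  npts <- vapply(rings, function(r) length(r$x) + 1L, integer(1))  # closed
  parts <- cumsum(c(0L, npts[-length(npts)]))
  bb <- geom_bbox(geom)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(as.numeric(bb[c("xmin", "ymin", "xmax", "ymax")]), con,
           size = 8, endian = "little")
  writeBin(c(length(rings), sum(npts)), con, size = 4, endian = "little")
  writeBin(as.integer(parts), con, size = 4, endian = "little")
  for (r in rings) {
    xy <- rbind(c(r$x, r$x[1]), c(r$y, r$y[1]))
    writeBin(as.numeric(xy), con, size = 8, endian = "little")
  }
  rawConnectionValue(con)
}

shp_header <- function(file_len_bytes, shape_type, bbox) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(c(9994L, 0L, 0L, 0L, 0L, 0L, as.integer(file_len_bytes / 2)),
           con, size = 4, endian = "big")
  writeBin(c(1000L, as.integer(shape_type)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(bbox[c("xmin", "ymin", "xmax", "ymax")], 0, 0, 0, 0)),
           con, size = 8, endian = "little")
  rawConnectionValue(con)
}

write_shapefile <- function(df, geoms, crs, path) {
  stopifnot(grepl("\\.shp$", path, ignore.case = TRUE))
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  contents <- lapply(geoms, shp_record_content)
  rec_bytes <- vapply(contents, length, integer(1))
  bbs <- vapply(geoms, geom_bbox, numeric(4))
  bbox <- c(xmin = min(bbs["xmin", ]), ymin = min(bbs["ymin", ]),
            xmax = max(bbs["xmax", ]), ymax = max(bbs["ymax", ]))
  # .shp
  shp_len <- 100L + sum(rec_bytes + 8L)
  con <- file(path, "wb")
  writeBin(shp_header(shp_len, 5L, bbox), con)
  for (i in seq_along(contents)) {
    writeBin(c(i, as.integer(rec_bytes[i] / 2)), con, size = 4, endian = "big")
    writeBin(contents[[i]], con)
  }
  close(con)
  # .shx
  shx_len <- 100L + 8L * length(contents)
  con <- file(paste0(base, ".shx"), "wb")
  writeBin(shp_header(shx_len, 5L, bbox), con)
  offset <- 50L  # header length in 16-bit words
  for (i in seq_along(contents)) {
    writeBin(c(offset, as.integer(rec_bytes[i] / 2)), con, size = 4,
             endian = "big")
    offset <- offset + as.integer((rec_bytes[i] + 8L) / 2)
  }
  close(con)
  # .dbf — logical NA is not representable portably; encode logicals as 0/1
  ddf <- df
  for (nm in names(ddf)) {
    if (is.logical(ddf[[nm]])) ddf[[nm]] <- as.integer(ddf[[nm]])
  }
  names(ddf) <- to_dbf_names(names(ddf))
  # write.dbf warns computing field widths for all-NA columns; harmless
  suppressWarnings(foreign::write.dbf(ddf, paste0(base, ".dbf")))
  # .prj (CRS identifier as plain text; WKT is out of scope)
  writeLines(crs, paste0(base, ".prj"))
  invisible(path)
}

read_shp_geoms <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, integer(), n = 6, size = 4, endian = "big")
  file_len_words <- readBin(con, integer(), n = 1, size = 4, endian = "big")
  readBin(con, integer(), n = 2, size = 4, endian = "little")
  readBin(con, numeric(), n = 8, size = 8, endian = "little")
  geoms <- list()
  words_read <- 50L
  while (words_read < file_len_words) {
    rec <- readBin(con, integer(), n = 2, size = 4, endian = "big")
    if (length(rec) < 2) break
    content_words <- rec[2]
    shape_type <- readBin(con, integer(), n = 1, size = 4, endian = "little")
    if (shape_type == 0L) {  # null shape
      geoms[[length(geoms) + 1L]] <- NULL
    } else if (shape_type == 5L) {
      readBin(con, numeric(), n = 4, size = 8, endian = "little")
      counts <- readBin(con, integer(), n = 2, size = 4, endian = "little")
      nparts <- counts[1]; npts <- counts[2]
      parts <- readBin(con, integer(), n = nparts, size = 4, endian = "little")
      xy <- readBin(con, numeric(), n = 2 * npts, size = 8, endian = "little")
      x <- xy[seq(1, 2 * npts, by = 2)]
      y <- xy[seq(2, 2 * npts, by = 2)]
      ends <- c(parts[-1], npts)
      rings <- lapply(seq_len(nparts), function(k) {
        idx <- (parts[k] + 1L):ends[k]
        rx <- x[idx]; ry <- y[idx]
        n <- length(rx)
        if (n > 1L && rx[1] == rx[n] && ry[1] == ry[n]) {
          rx <- rx[-n]; ry <- ry[-n]
        }
        list(x = rx, y = ry)
      })
      geoms[[length(geoms) + 1L]] <- rings
    } else {
      stop("unsupported shapefile shape type: ", shape_type, call. = FALSE)
    }
    words_read <- words_read + 4L + content_words
  }
  geoms
}

read_shapefile <- function(path) {
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  geoms <- read_shp_geoms(path)
  dbf_path <- paste0(base, ".dbf")
  if (file.exists(dbf_path)) {
    df <- foreign::read.dbf(dbf_path, as.is = TRUE)
    names(df) <- from_dbf_names(names(df))
  } else {
    df <- data.frame(row.names = seq_along(geoms))
  }
  for (nm in intersect(c("insecticide", "escalated"), names(df))) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  if ("risk_class" %in% names(df)) df$risk_class <- as.numeric(df$risk_class)
  prj_path <- paste0(base, ".prj")
  crs_id <- if (file.exists(prj_path)) trimws(readLines(prj_path, n = 1)) else NULL
  df$geometry <- geoms
  list(df = df, crs_id = crs_id)
}
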