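Package: rotadist
Title: Pest-Specific Crop Rotation Distance Planning and Risk Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for area-wide crop rotation planning against
    insect pests that overwinter at previous-year crop sites, using the pea
    moth (Cydia nigricana) on peas (Pisum sativum) as the model system. Fits
    the exponential infestation-distance decay model y = a*exp(-MD/b) to
    observations of percent seed infestation versus minimum edge-to-edge
    rotation distance, derives pest-specific risk-buffer distances from the
    fitted decay scale and its standard error, builds area-wide risk maps by
    ring-buffering previous-year crop polygons, classing the rings, and
    escalating risk where buffers from several sources overlap, and answers
    point queries for planned field locations with a clipped local risk map
    and bearings to risk sources. Includes vector I/O (GeoJSON and ESRI
    Shapefile), a reproducible synthetic landscape generator for testing, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    foreign,
    geosphere,
    grDevices,
    jsonlite,
    minpack.lm,
    polyclip,
    sp,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
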