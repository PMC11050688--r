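# Pipeline orchestration: fit (or accept published estimates), derive the
# buffer distances, build the flat risk map, optionally answer a query, and
# write every artifact to an output directory. The whole run is a pure
# function of (inputs, config, seed).

#' Run the crop-rotation risk-mapping pipeline
#'
#' Stages, each skipped when its inputs are absent from the config:
#' 1. read previous-year site polygons (`previous`: path or in-memory
#'    layer);
#' 2. fit the decay model to observations (`observations`: CSV path or data
#'    frame, split by its `insecticide` column into all/untreated groups),
#'    or accept pre-supplied `estimates` (`list(all = list(b, se_b),
#'    no_insecticide = list(b, se_b))`) without refitting;
#' 3. derive inner/middle/outer buffer distances from the fits/estimates,
#'    otherwise fall back to the default grain-pea scheme;
#' 4. build per-crop ring buffers and flatten with escalation;
#' 5. optionally answer a risk query (`query`: `list(x, y, radius_m)`).
#'
#' Artifacts written to `out_dir`: `risk_map.geojson`, `report.json` (fits,
#' derivation, zone bookkeeping) and, when queried, `query_window.geojson`
#' plus `query.json`. Stage errors are rethrown tagged with the stage name.
#'
#' @param config Named list, or path to a YAML/JSON config file with the
#'   keys above plus optional `crop_schemes` (per-crop `distances_m` /
#'   `classes` / `ladder` / `escalation`), `segments` and `out_dir`.
#' @return Invisibly, a list with `map`, `report`, `fits`, `derivation`,
#'   `query` and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  out_dir <- config$out_dir %||% tempfile("rotadist_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  previous <- stage("read-previous", {
    p <- config$previous
    if (is.character(p)) read_layer(p) else p
  })
  if (is.null(previous)) stop("config must name a previous-year layer",
                              call. = FALSE)

  fits <- NULL
  derivation <- NULL
  if (!is.null(config$observations)) {
    fits <- stage("fit-decay", {
      obs <- config$observations
      if (is.character(obs)) obs <- read_observations(obs)
      f_all <- fit_decay(obs)
      f_untreated <- if ("insecticide" %in% names(obs) &&
                         any(!obs$insecticide, na.rm = TRUE)) {
        fit_decay(obs[which(!obs$insecticide), , drop = FALSE])
      } else NULL
      list(all = f_all, no_insecticide = f_untreated)
    })
    if (!is.null(fits$no_insecticide)) {
      derivation <- stage("derive-buffers",
                          derive_buffers(fits$all, fits$no_insecticide))
    }
  } else if (!is.null(config$estimates)) {
    derivation <- stage("derive-buffers", derive_buffers(
      config$estimates$all, config$estimates$no_insecticide))
  }

  schemes <- stage("schemes", {
    if (!is.null(config$crop_schemes)) {
      lapply(config$crop_schemes, scheme_from_config)
    } else {
      list(grain_pea = grain_pea_scheme(derivation),
           green_pea = green_pea_scheme(),
           other = grain_pea_scheme(derivation))
    }
  })
  segments <- config$segments %||% 16L

  map <- stage("risk-map", build_risk_map(previous, schemes,
                                          segments = segments,
                                          ladder_scheme = schemes[[1]]))
  paths$risk_map <- file.path(out_dir, "risk_map.geojson")
  stage("write-risk-map", write_layer(map, paths$risk_map))

  qres <- NULL
  if (!is.null(config$query)) {
    qres <- stage("query", query_risk(map, previous,
                                      x = config$query$x, y = config$query$y,
                                      radius_m = config$query$radius_m,
                                      scheme = schemes))
    paths$query_json <- file.path(out_dir, "query.json")
    query_json(qres, paths$query_json)
    if (nrow(qres$local_map) > 0L) {
      paths$query_window <- file.path(out_dir, "query_window.geojson")
      write_layer(qres$local_map, paths$query_window)
    }
  }

  report <- list(
    n_previous_sites = nrow(previous),
    crs_id = layer_crs(previous),
    fits = if (!is.null(fits))
      lapply(fits[!vapply(fits, is.null, logical(1))], unclass),
    derivation = if (!is.null(derivation)) unclass(derivation),
    schemes = lapply(schemes, unclass),
    n_zones = nrow(map),
    classes = sort(unique(map$risk_class)),
    query = if (!is.null(qres))
      list(class_at_point = qres$class_at_point, n_sources = nrow(qres$sources))
  )
  paths$report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  message("rotadist pipeline: ", nrow(map), " zones written to ", out_dir)
  invisible(list(map = map, report = report, fits = fits,
                 derivation = derivation, query = qres, paths = paths))
}
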