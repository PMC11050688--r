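# Risk schemes: buffer distances paired with risk classes and an escalation
# ladder. Risk classes decrease with distance from a previous-year crop
# site; where buffers from at least two distinct sources overlap, the class
# is raised to the next value up the ladder (saturating at the ladder
# maximum).

#' Construct a risk scheme
#'
#' @param distances_m Strictly increasing buffer distances in meters; band
#'   `i` spans from `distances_m[i-1]` (0 for the first, which includes the
#'   source polygon itself) out to `distances_m[i]`.
#' @param classes Risk-class value per band, strictly decreasing outward;
#'   every value must be a member of `ladder`.
#' @param ladder Ordered admissible class values used for escalation, e.g.
#'   linear `1:4` or exponential `c(1, 2, 4, 8)`. The cap is `max(ladder)`.
#' @param escalation `"one-step"` (default): any region covered by two or
#'   more distinct sources moves one ladder step up from the maximum
#'   covering class. `"per-source-step"`: a region covered by `k` sources
#'   moves `k - 1` steps.
#' @return A `risk_scheme` list.
#' @export
risk_scheme <- function(distances_m, classes, ladder = c(1, 2, 4, 8),
                        escalation = c("one-step", "per-source-step")) {
  escalation <- match.arg(escalation)
  distances_m <- as.numeric(distances_m)
  classes <- as.numeric(classes)
  ladder <- as.numeric(ladder)
  if (length(distances_m) < 1L || length(distances_m) != length(classes)) {
    stop("distances_m and classes must have equal positive length",
         call. = FALSE)
  }
  if (any(distances_m <= 0) || any(diff(distances_m) <= 0)) {
    stop("distances_m must be positive and strictly increasing", call. = FALSE)
  }
  if (length(classes) > 1L && any(diff(classes) >= 0)) {
    stop("classes must be strictly decreasing outward (risk decreases with ",
         "distance)", call. = FALSE)
  }
  if (any(diff(ladder) <= 0)) {
    stop("ladder must be strictly increasing", call. = FALSE)
  }
  if (!all(classes %in% ladder)) {
    stop("every class must be a member of the ladder", call. = FALSE)
  }
  structure(list(distances_m = distances_m, classes = classes,
                 ladder = ladder, cap = max(ladder), escalation = escalation),
            class = "risk_scheme")
}

#' Linear and exponential class ladders
#'
#' @param n Number of ladder values.
#' @return Numeric vector: `1:n` (linear) or `2^(0:(n-1))` (exponential).
#' @export
linear_ladder <- function(n) as.numeric(seq_len(n))

#' @rdname linear_ladder
#' @export
exponential_ladder <- function(n) 2^(0:(n - 1))

# Next ladder value above `class`, saturating at the cap; `steps` ladder
# steps at once for the per-source-step mode.
next_class <- function(scheme, class, steps = 1L) {
  i <- match(class, scheme$ladder)
  if (is.na(i)) stop("class ", class, " not in ladder", call. = FALSE)
  scheme$ladder[min(i + steps, length(scheme$ladder))]
}

#' Default grain-pea risk scheme
#'
#' Three concentric bands at the derived grain-pea buffer distances
#' (1261 / 1560 / 1825 m by default) classed 4 / 2 / 1 on the exponential
#' ladder 1, 2, 4, 8.
#'
#' @param derivation Optional `buffer_derivation` supplying the three
#'   distances (e.g. from [derive_buffers()]).
#' @param escalation Escalation mode, see [risk_scheme()].
#' @return A `risk_scheme`.
#' @export
grain_pea_scheme <- function(derivation = NULL,
                             escalation = c("one-step", "per-source-step")) {
  d <- if (is.null(derivation)) c(1261, 1560, 1825) else
    c(derivation$inner_m, derivation$middle_m, derivation$outer_m)
  risk_scheme(d, classes = c(4, 2, 1), ladder = c(1, 2, 4, 8),
              escalation = match.arg(escalation))
}

#' Default green-pea risk scheme
#'
#' A single 500 m safety band (class 2 on the exponential ladder): green
#' peas are harvested immature, interrupting the pest life cycle, so only a
#' small fixed buffer is warranted.
#'
#' @param escalation Escalation mode, see [risk_scheme()].
#' @return A `risk_scheme`.
#' @export
green_pea_scheme <- function(escalation = c("one-step", "per-source-step")) {
  risk_scheme(GREEN_PEA_BUFFER_M, classes = 2, ladder = c(1, 2, 4, 8),
              escalation = match.arg(escalation))
}

#' @export
print.risk_scheme <- function(x, ...) {
  cat("<risk_scheme>\n  bands: ",
      paste(sprintf("<=%gm:class %g", x$distances_m, x$classes),
            collapse = ", "),
      "\n  ladder: ", paste(x$ladder, collapse = " < "),
      " (cap ", x$cap, "), escalation: ", x$escalation, "\n", sep = "")
  invisible(x)
}

#' Read a risk scheme from a JSON or YAML config file
#'
#' Keys: `distances_m`, `classes`, `ladder` (optional), `escalation`
#' (optional).
#'
#' @param path Config file path (`.json`, `.yaml` or `.yml`).
#' @return A `risk_scheme`.
#' @export
read_scheme <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  scheme_from_config(cfg)
}

scheme_from_config <- function(cfg) {
  risk_scheme(cfg$distances_m, cfg$classes,
              ladder = cfg$ladder %||% c(1, 2, 4, 8),
              escalation = cfg$escalation %||% "one-step")
}
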