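# Infestation-distance decay model.
#
# Pests that overwinter in the soil of previous-year crop sites must migrate
# to the nearest current-year host site in spring. Percent seed infestation
# y declines with the minimum edge-to-edge rotation distance MD (meters) as
#
#     y = a * exp(-MD / b)
#
# where a is the infestation at MD = 0 (percent) and b the e-folding
# distance (meters): the distance over which predicted infestation falls by
# a factor 1/e. b and its standard error drive the recommended risk-buffer
# distances.

#' Predicted percent infestation at a given rotation distance
#'
#' Evaluates the exponential decay curve `y = a * exp(-md / b)`.
#'
#' @param a Infestation at distance zero, percent (> 0).
#' @param b Decay scale (e-folding distance) in meters (> 0).
#' @param md Minimum rotation distance(s) in meters (>= 0).
#' @return Predicted infestation in percent, strictly decreasing in `md`.
#' @examples
#' predict_infestation(9.79, 1260.70, 0)       # the y-intercept
#' predict_infestation(9.79, 1260.70, 1260.70) # a / e
#' @export
predict_infestation <- function(a, b, md) {
  if (!is.numeric(a) || a <= 0) stop("a must be > 0 (percent)", call. = FALSE)
  if (!is.numeric(b) || b <= 0) stop("b must be > 0 (meters)", call. = FALSE)
  if (any(md < 0)) stop("md must be >= 0", call. = FALSE)
  a * exp(-md / b)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Fit the exponential infestation-distance decay model
#'
#' Nonlinear least squares for `y = a * exp(-md / b)` via Levenberg-Marquardt
#' with box bounds `a` in (0, 100] (percent scale) and `b` in (0, 1e6] m.
#' Standard errors come from the estimated parameter covariance; p-values
#' from `t = estimate / SE` on `n - 2` degrees of freedom. RMSE uses the
#' regression convention `sqrt(SSE / (n - 2))`; the adjusted R-squared is
#' `1 - (1 - R2) (n - 1) / (n - 3)` with R2 taken against the mean-only
#' model. Both conventions are stated here because the quantities are often
#' printed without definition.
#'
#' @param observations Data frame with numeric columns `md_m` (minimum
#'   rotation distance, meters, >= 0) and `infestation_pct` (percent seed
#'   infestation in `[0, 100]`); an optional `insecticide` column is carried
#'   along for group subsetting by the caller.
#' @param start Optional named list `list(a =, b =)` of start values.
#'   Defaults: `a = max(y)`, `b = max(md) / 2`, robust for decay data.
#' @param max_iter Iteration cap for the optimizer (default 200).
#' @param check_domain When `TRUE` (default) observed infestation must lie
#'   in the percent domain `[0, 100]`. Set `FALSE` for simulation studies
#'   whose unbounded Gaussian errors can push simulated responses below
#'   zero; truncating such draws at zero instead inflates the far tail and
#'   biases the decay scale upward (see the methods vignette).
#' @return An object of class `decay_fit`: a list with elements `a`, `b`,
#'   `se_a`, `se_b`, `p_a`, `p_b`, `rmse`, `r2_adj`, `n`, `df`,
#'   `convergence` and `observations`.
#' @export
fit_decay <- function(observations, start = NULL, max_iter = 200L,
                      check_domain = TRUE) {
  stopifnot(is.data.frame(observations),
            all(c("md_m", "infestation_pct") %in% names(observations)))
  md <- as.numeric(observations$md_m)
  y <- as.numeric(observations$infestation_pct)
  keep <- is.finite(md) & is.finite(y)
  md <- md[keep]; y <- y[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(md < 0)) stop("md_m must be >= 0", call. = FALSE)
  if (check_domain && any(y < 0 | y > 100)) {
    stop("infestation_pct must lie in [0, 100]", call. = FALSE)
  }
  if (length(unique(md)) < 2L) {
    stop("need at least 2 distinct md_m values", call. = FALSE)
  }
  if (all(y <= 0)) {
    stop("degenerate: no positive infestation; the decay curve is ",
         "unidentifiable (use the fixed green-pea safety buffer instead)",
         call. = FALSE)
  }
  if (is.null(start)) start <- list(a = max(y), b = max(md) / 2)
  dat <- data.frame(md = md, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-md / b), data = dat, start = start,
      lower = c(a = 1e-9, b = 1e-9), upper = c(a = 100, b = 1e6),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) {
      stop("decay fit did not converge (start a = ", format(start$a),
           ", b = ", format(start$b), "): ", conditionMessage(e),
           call. = FALSE)
    })
  cf <- summary(fit)$coefficients
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  out <- list(
    a = unname(cf["a", "Estimate"]), b = unname(cf["b", "Estimate"]),
    se_a = unname(cf["a", "Std. Error"]), se_b = unname(cf["b", "Std. Error"]),
    p_a = unname(cf["a", "Pr(>|t|)"]), p_b = unname(cf["b", "Pr(>|t|)"]),
    rmse = sqrt(sse / (n - 2)),
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 3),
    n = n, df = n - 2L,
    convergence = fit$convInfo$isConv %||% TRUE
  )
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential infestation-distance decay fit  y = a * exp(-MD/b)\n")
  cat(sprintf("  a  = %8.2f %%  (SE %.2f) %s\n", x$a, x$se_a,
              significance_stars(x$p_a)))
  cat(sprintf("  b  = %8.2f m  (SE %.2f) %s\n", x$b, x$se_b,
              significance_stars(x$p_b)))
  cat(sprintf("  RMSE = %.2f %%   adj. R2 = %.2f   n = %d\n",
              x$rmse, x$r2_adj, x$n))
  invisible(x)
}

#' Serialize a decay fit to a JSON report
#'
#' @param fit A `decay_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly the path when written to file).
#' @export
decay_fit_json <- function(fit, path = NULL) {
  payload <- unclass(fit)
  payload$sig_a <- significance_stars(fit$p_a)
  payload$sig_b <- significance_stars(fit$p_b)
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive risk-buffer distances from decay fits
#'
#' The three recommended concentric risk-buffer distances:
#' * inner: `b` of the fit to all sites,
#' * middle: `b + SE(b)` of the fit to all sites,
#' * outer: `b + SE(b)` of the fit to untreated (no-insecticide) sites, the
#'   worst case relevant when the treatment status of previous sites is
#'   unknown or for organic cultivation.
#'
#' Distances are rounded half-away-from-zero to whole meters. With the
#' published grain-pea estimates (`b = 1260.70`, SE `299.45`; untreated
#' `b = 1426.23`, SE `398.92`) this yields 1261 / 1560 / 1825 m.
#'
#' @param fit_all `decay_fit` (or list with `b`, `se_b`) for all sites.
#' @param fit_no_insecticide `decay_fit` (or list with `b`, `se_b`) for
#'   untreated sites.
#' @return A `buffer_derivation`: list with integer `inner_m`, `middle_m`,
#'   `outer_m`.
#' @export
derive_buffers <- function(fit_all, fit_no_insecticide) {
  stopifnot(is.numeric(fit_all$b), is.numeric(fit_all$se_b),
            is.numeric(fit_no_insecticide$b),
            is.numeric(fit_no_insecticide$se_b))
  out <- list(
    inner_m = as.integer(round_half_up(fit_all$b)),
    middle_m = as.integer(round_half_up(fit_all$b + fit_all$se_b)),
    outer_m = as.integer(round_half_up(fit_no_insecticide$b +
                                         fit_no_insecticide$se_b))
  )
  if (!(out$inner_m <= out$middle_m && out$middle_m <= out$outer_m)) {
    warning("derived buffers are not ordered inner <= middle <= outer ",
            "(data-dependent); check the group fits", call. = FALSE)
  }
  class(out) <- "buffer_derivation"
  out
}

#' @export
print.buffer_derivation <- function(x, ...) {
  cat(sprintf("Risk buffers: inner %d m | middle %d m | outer %d m\n",
              x$inner_m, x$middle_m, x$outer_m))
  invisible(x)
}

#' Fixed safety buffer for green peas, meters
#'
#' Green peas are harvested immature (around BBCH 79), which interrupts the
#' pea moth life cycle; observed mean infestation is too low (0.11 percent)
#' to fit the decay curve, so a fixed 500 m safety buffer is used instead.
#'
#' @export
GREEN_PEA_BUFFER_M <- 500

#' Published decay-model estimates for the pea moth on grain peas
#'
#' Parameter estimates of the infestation-distance decay model from the
#' 2016-2019 German pea moth monitoring (three pea-growing regions, 513
#' monitored sites), fitted separately to all grain-pea sites and to the
#' insecticide-treated and untreated subsets. Significance codes:
#' `***` p < 0.001, `**` p < 0.01.
#'
#' @return Tibble with columns `group`, `a`, `se_a`, `sig_a`, `b`, `se_b`,
#'   `sig_b`, `rmse`, `r2_adj`, `n`.
#' @export
pea_moth_decay_estimates <- function() {
  tibble::tibble(
    group = c("all", "no_insecticide", "insecticide"),
    a = c(9.79, 12.85, 8.13),
    se_a = c(0.92, 1.45, 1.09),
    sig_a = c("***", "***", "***"),
    b = c(1260.70, 1426.23, 619.05),
    se_b = c(299.45, 398.92, 187.02),
    sig_b = c("***", "**", "**"),
    rmse = c(9.10, 9.98, 7.41),
    r2_adj = c(0.05, 0.08, 0.07),
    n = c(370L, 188L, 182L)
  )
}

#' Monitoring sample-site counts by region, year, crop and treatment
#'
#' Bookkeeping of the 2016-2019 monitoring: number of sampled pea sites per
#' German federal state (ST = Saxony-Anhalt, SN = Saxony, HE = Hesse), year,
#' crop type and insecticide treatment. Totals: 513 sites overall; 182
#' insecticide-treated and 188 untreated grain-pea sites.
#'
#' @return Tibble with columns `state`, `year`, `crop`, `insecticide`,
#'   `n_sites`.
#' @export
pea_monitoring_site_counts <- function() {
  grain <- rbind(
    c("ST", 2016, 57, 1), c("ST", 2017, 50, 3), c("ST", 2018, 32, 9),
    c("SN", 2016, 7, 21), c("SN", 2017, 4, 15), c("SN", 2018, 2, 9),
    c("SN", 2019, 2, 6),
    c("HE", 2016, 3, 31), c("HE", 2017, 14, 44), c("HE", 2018, 11, 34),
    c("HE", 2019, 0, 15))
  green <- rbind(
    c("SN", 2016, 33, 19), c("SN", 2017, 13, 24), c("SN", 2018, 20, 32),
    c("SN", 2019, 0, 2))
  mk <- function(m, crop) {
    tibble::tibble(
      state = rep(m[, 1], 2),
      year = as.integer(rep(m[, 2], 2)),
      crop = crop,
      insecticide = rep(c(TRUE, FALSE), each = nrow(m)),
      n_sites = as.integer(c(m[, 3], m[, 4]))
    )
  }
  out <- rbind(mk(grain, "grain_pea"), mk(green, "green_pea"))
  out[out$n_sites >= 0, ]
}

#' Read distance-infestation observations from CSV
#'
#' Expects columns `md_m` and `infestation_pct`, optionally `insecticide`
#' (logical or 0/1).
#'
#' @param path CSV file path.
#' @return Tibble of observations.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("md_m", "infestation_pct") %in% names(df))) {
    stop("observations CSV needs columns md_m and infestation_pct",
         call. = FALSE)
  }
  if ("insecticide" %in% names(df)) df$insecticide <- as.logical(df$insecticide)
  tibble::as_tibble(df)
}
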