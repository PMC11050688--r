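# Exponential infestation-distance decay model: prediction, fitting,
# buffer derivation.

test_that("predict_infestation evaluates the closed form", {
  expect_equal(predict_infestation(9.79, 1260.70, 0), 9.79)
  expect_equal(predict_infestation(9.79, 1260.70, 1260.70), 9.79 / exp(1))
  expect_lt(predict_infestation(9.79, 1260.70, 3e7), 1e-6)
  expect_error(predict_infestation(9.79, -1, 100), "b must be")
  expect_error(predict_infestation(0, 1260.7, 100), "a must be")
  expect_error(predict_infestation(9.79, 1260.7, -5), "md")
})

test_that("predicted infestation is strictly decreasing in distance", {
  set.seed(21)
  for (rep in 1:50) {
    a <- stats::runif(1, 0.5, 50); b <- stats::runif(1, 100, 5000)
    md <- sort(stats::runif(2, 0, 10000))
    expect_gt(predict_infestation(a, b, md[1]),
              predict_infestation(a, b, md[2]))
  }
})

test_that("fit on noiseless curve data recovers the generating parameters", {
  md <- seq(0, 4900, by = 100)
  obs <- data.frame(md_m = md, infestation_pct = 9.79 * exp(-md / 1260.70))
  f <- fit_decay(obs)
  expect_equal(f$a, 9.79, tolerance = 1e-7)
  expect_equal(f$b, 1260.70, tolerance = 1e-7)
  expect_lt(f$rmse, 1e-6)
  expect_equal(f$n, 50L)
  expect_gt(f$r2_adj, 0.999)
})

test_that("degenerate and undersized inputs error explicitly", {
  expect_error(fit_decay(data.frame(md_m = c(0, 100, 200),
                                    infestation_pct = c(0, 0, 0))),
               "degenerate")
  expect_error(fit_decay(data.frame(md_m = c(0, 100),
                                    infestation_pct = c(5, 3))),
               "at least 3")
  expect_error(fit_decay(data.frame(md_m = c(100, 100, 100),
                                    infestation_pct = c(5, 4, 3))),
               "distinct")
  expect_error(fit_decay(data.frame(md_m = c(0, 100, 200),
                                    infestation_pct = c(5, 101, 3))),
               "\\[0, 100\\]")
})

test_that("rescaling distances rescales b and leaves a untouched", {
  set.seed(5)
  md <- runif(80, 0, 3000)
  y <- pmax(0, 9.79 * exp(-md / 1260.7) + rnorm(80, 0, 2))
  f1 <- fit_decay(data.frame(md_m = md, infestation_pct = y))
  for (c_scale in c(0.1, 3.7)) {
    f2 <- fit_decay(data.frame(md_m = md * c_scale, infestation_pct = y))
    expect_equal(f2$b, f1$b * c_scale, tolerance = 1e-6)
    expect_equal(f2$a, f1$a, tolerance = 1e-6)
  }
})

test_that("fit statistics follow the stated conventions", {
  set.seed(9)
  md <- runif(40, 0, 3000)
  y <- pmax(0, 9.79 * exp(-md / 1260.7) + rnorm(40, 0, 3))
  f <- fit_decay(data.frame(md_m = md, infestation_pct = y))
  yhat <- predict_infestation(f$a, f$b, md)
  sse <- sum((y - yhat)^2)
  expect_equal(f$rmse, sqrt(sse / (40 - 2)), tolerance = 1e-8)
  r2 <- 1 - sse / sum((y - mean(y))^2)
  expect_equal(f$r2_adj, 1 - (1 - r2) * 39 / 37, tolerance = 1e-8)
  expect_true(f$se_a > 0 && f$se_b > 0)
  expect_true(f$p_b >= 0 && f$p_b <= 1)
})

test_that("buffer derivation rounds half away from zero and orders bands", {
  d <- derive_buffers(list(b = 1260.70, se_b = 299.45),
                      list(b = 1426.23, se_b = 398.92))
  expect_identical(c(d$inner_m, d$middle_m, d$outer_m), c(1261L, 1560L, 1825L))
  d0 <- derive_buffers(list(b = 1000.0, se_b = 0.0),
                       list(b = 1000.0, se_b = 0.0))
  expect_identical(c(d0$inner_m, d0$middle_m, d0$outer_m),
                   c(1000L, 1000L, 1000L))
  dh <- derive_buffers(list(b = 1000.4, se_b = 0.2),
                       list(b = 2000.0, se_b = 0.6))
  expect_identical(c(dh$inner_m, dh$middle_m, dh$outer_m),
                   c(1000L, 1001L, 2001L))
  expect_warning(derive_buffers(list(b = 2000, se_b = 10),
                                list(b = 500, se_b = 10)),
                 "ordered")
})

test_that("published estimate and monitoring-count tables are consistent", {
  est <- pea_moth_decay_estimates()
  expect_equal(est$group, c("all", "no_insecticide", "insecticide"))
  expect_true(all(est$a > 0 & est$b > 0 & est$se_b > 0))
  cnt <- pea_monitoring_site_counts()
  grain <- cnt[cnt$crop == "grain_pea", ]
  # subset n in the estimates table match the monitoring bookkeeping
  expect_equal(sum(grain$n_sites[!grain$insecticide]),
               est$n[est$group == "no_insecticide"])
  expect_equal(sum(grain$n_sites[grain$insecticide]),
               est$n[est$group == "insecticide"])
  expect_equal(sum(grain$n_sites), est$n[est$group == "all"])
})

test_that("fit report serializes to JSON with significance codes", {
  md <- seq(0, 4900, by = 100)
  f <- fit_decay(data.frame(md_m = md,
                            infestation_pct = 9.79 * exp(-md / 1260.70)))
  j <- jsonlite::fromJSON(decay_fit_json(f))
  expect_equal(j$a, f$a)
  expect_equal(j$sig_b, "***")
  expect_output(print(f), "e-folding|a  =")
})

test_that("observation CSV reader enforces the schema", {
  p <- file.path(tempdir(), "obs.csv")
  write.csv(data.frame(md_m = c(0, 10), infestation_pct = c(9, 8),
                       insecticide = c(0, 1)), p, row.names = FALSE)
  obs <- read_observations(p)
  expect_identical(obs$insecticide, c(FALSE, TRUE))
  write.csv(data.frame(x = 1), p, row.names = FALSE)
  expect_error(read_observations(p), "md_m")
})
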