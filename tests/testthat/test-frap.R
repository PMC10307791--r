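test_that("double normalization reproduces the underlying recovery exactly", {
  # corrections are no-ops without photobleaching or background
  sim <- simulate_frap_series(tau = 3, photobleach_rate = 0, noise_sigma = 0)
  norm <- normalize_frap_trace(sim$trace, "in_vivo")
  post <- norm$phase == "post"
  r <- 0.9 + (0.3 - 0.9) * exp(-norm$time_min[post] / 3)
  expect_equal(norm$normalized[post], 100 * r, tolerance = 1e-12)

  # multiplicative acquisition decay cancels exactly
  simb <- simulate_frap_series(tau = 3, photobleach_rate = 0.08,
                               background_level = 20, noise_sigma = 0)
  normb <- normalize_frap_trace(simb$trace, "in_vivo")
  expect_lt(max(abs(normb$normalized[post] - 100 * r)), 1e-10)

  # pre-bleach frames anchor to exactly 100
  expect_equal(mean(normb$normalized[normb$phase == "pre"]), 100)
})

test_that("normalization anchors arbitrary pre-bleach values to mean 100", {
  tr <- tibble::tibble(
    time_min = c(-2, -1, 0, 1, 2, 3, 4, 5),
    phase = rep(c("pre", "post"), c(2, 6)),
    roi = c(98, 102, 50, 55, 60, 64, 67, 70),
    roi_bg = 0, cell = 100, cell_bg = 0
  )
  norm <- normalize_frap_trace(tr, "in_vivo")
  expect_equal(mean(norm$normalized[norm$phase == "pre"]), 100)
  expect_equal(norm$normalized[3], 100 * 50 / 100)

  # in vitro: ROI alone, halved signal -> 50
  norm2 <- normalize_frap_trace(tr, "in_vitro")
  expect_equal(norm2$normalized[3], 50)

  bad <- tr
  bad$cell[5] <- 0
  expect_error(normalize_frap_trace(bad, "in_vivo"), "frame 5")
})

test_that("exponential fit recovers noiseless parameters and t_half = t log 2", {
  x <- seq(0, 20, by = 0.25)
  y <- 90 - 60 * exp(-x / 3)
  fit <- fit_frap_recovery(y, time = x)
  expect_true(fit$converged)
  expect_equal(fit$y0, 90, tolerance = 1e-6)
  expect_equal(fit$A, -60, tolerance = 1e-6)
  expect_equal(fit$t, 3, tolerance = 1e-6)
  expect_equal(fit$t_half, 3 * log(2), tolerance = 1e-6)
  expect_equal(fit$t_half / fit$t, log(2))

  expect_error(fit_frap_recovery(y[1:4], time = x[1:4]), ">= 5")
})

test_that("flat series are flagged unidentifiable, not errored", {
  fit <- fit_frap_recovery(rep(80, 30), time = seq(0, 29))
  expect_false(fit$converged)
  expect_match(fit$note, "flat")
  expect_true(is.na(fit$t_half))
})

test_that("median fitted t is within 5% of truth at 2% noise", {
  est <- vapply(1:60, function(s) {
    sim <- simulate_frap_series(tau = 3, noise_sigma = 2, seed = s)
    fit_frap_recovery(normalize_frap_trace(sim$trace, "in_vivo"))$t
  }, numeric(1))
  expect_lt(abs(stats::median(est, na.rm = TRUE) - 3) / 3, 0.05)
})

test_that("tidy and glance summarise fits as tibbles", {
  x <- seq(0, 20, by = 0.5)
  fit <- fit_frap_recovery(90 - 60 * exp(-x / 2), time = x)
  td <- tidy(fit)
  expect_equal(td$term, c("y0", "A", "t", "t_half"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
})

test_that("aggregation averages events on a common grid and pools the fit", {
  mk <- function(offset = 0, seed = 1) {
    sim <- simulate_frap_series(tau = 2.3, noise_sigma = 0, seed = seed)
    tr <- normalize_frap_trace(sim$trace, "in_vivo")
    tr$normalized <- tr$normalized + offset
    tr
  }
  # identical traces: SD 0 everywhere, pooled fit equals the individual fit
  agg <- aggregate_frap(list(mk(), mk(), mk()))
  expect_true(all(agg$curve$stdev < 1e-10))
  # equality up to the common-grid linear resampling of the exponential
  expect_equal(agg$pooled_fit$t, agg$event_fits$t[1], tolerance = 0.01)

  # symmetric offsets: mean equals the central trace
  agg2 <- aggregate_frap(list(mk(+2), mk(-2)))
  central <- mk(0)
  interp <- stats::approx(central$time_min[central$phase == "post"],
                          central$normalized[central$phase == "post"],
                          xout = agg2$curve$time_min)$y
  expect_equal(agg2$curve$mean, interp, tolerance = 1e-8)

  # pooled t_half from simulated events is close to truth
  events <- lapply(1:7, function(s) {
    normalize_frap_trace(simulate_frap_series(tau = 2.3, noise_sigma = 1,
                                              seed = s)$trace, "in_vivo")
  })
  agg3 <- aggregate_frap(events)
  expect_lt(abs(agg3$pooled_fit$t_half - 2.3 * log(2)) / (2.3 * log(2)), 0.1)

  expect_error(aggregate_frap(list(mk())), ">= 2")
})
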