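test_that("control subtraction is pointwise and interpolates mismatched grids", {
  tr <- tibble::tibble(time_min = 0:10, a340 = 0.8 - 0.001 * (0:10))
  expect_true(all(subtract_control(tr, tr)$a340 == 0))

  ctrl <- tibble::tibble(time_min = 0:10, a340 = rep(0.05, 11))
  expect_equal(subtract_control(tr, ctrl)$a340, tr$a340 - 0.05)

  ctrl2 <- tibble::tibble(time_min = seq(0, 10, 0.5),
                          a340 = 0.1 - 0.002 * seq(0, 10, 0.5))
  out <- subtract_control(tr, ctrl2)
  expect_equal(out$a340, (0.8 - 0.001 * (0:10)) - (0.1 - 0.002 * (0:10)))

  far <- tibble::tibble(time_min = 100:110, a340 = rep(0.1, 11))
  expect_error(subtract_control(tr, far), "overlap")
})

test_that("Beer-Lambert conversion round-trips the generated rate", {
  # hand computation: slope -6220 * 0.248 * 1e-6 ~ -1.543e-3 AU/min -> 1 uM/min
  sim <- simulate_absorbance_trace(nadh_rate = 1e-6, noise_sigma = 0)
  rx <- sim$traces[sim$traces$trace == "reaction", ]
  ct <- sim$traces[sim$traces$trace == "control", ]
  corr <- subtract_control(rx, ct)
  res <- suppressWarnings(hydrolysis_rate(corr, enzyme_uM = 2))
  expect_equal(res$slope_au_per_min, -6220 * 0.248 * 1e-6, tolerance = 1e-9)
  expect_equal(res$nadh_rate_uM_min, 1, tolerance = 1e-9)
  expect_equal(res$specific_activity_per_min, 0.5, tolerance = 1e-9)

  # zero enzymatic rate -> flat corrected trace, rate 0
  sim0 <- simulate_absorbance_trace(nadh_rate = 0, noise_sigma = 0)
  corr0 <- subtract_control(sim0$traces[sim0$traces$trace == "reaction", ],
                            sim0$traces[sim0$traces$trace == "control", ])
  expect_equal(suppressWarnings(hydrolysis_rate(corr0)$nadh_rate_uM_min), 0,
               tolerance = 1e-12)
})

test_that("doubling the rate doubles the estimate and noise leaves it unbiased", {
  # fixed fit window: the automatic max-|slope| window is for skipping lag
  # phases and carries a small selection bias under noise
  rate_of <- function(v, noise = 0, seed = 1) {
    sim <- simulate_absorbance_trace(nadh_rate = v, noise_sigma = noise,
                                     seed = seed)
    corr <- subtract_control(sim$traces[sim$traces$trace == "reaction", ],
                             sim$traces[sim$traces$trace == "control", ])
    suppressWarnings(hydrolysis_rate(corr, window = c(0, 120)))$nadh_rate_uM_min
  }
  expect_equal(rate_of(2e-6), 2 * rate_of(1e-6), tolerance = 1e-9)

  est <- vapply(1:50, function(s) rate_of(1e-6, noise = 0.002, seed = s),
                numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 3 * se + 0.02)
})

test_that("subtracting then fitting equals the difference of fitted slopes", {
  sim <- simulate_absorbance_trace(nadh_rate = 1.5e-6, noise_sigma = 0.002,
                                   seed = 5)
  rx <- sim$traces[sim$traces$trace == "reaction", ]
  ct <- sim$traces[sim$traces$trace == "control", ]
  w <- c(0, 120)
  s_corr <- hydrolysis_rate(subtract_control(rx, ct), window = w)$slope_au_per_min
  s_rx <- hydrolysis_rate(rx, window = w)$slope_au_per_min
  s_ct <- suppressWarnings(hydrolysis_rate(ct, window = w))$slope_au_per_min
  expect_equal(s_corr, s_rx - s_ct, tolerance = 1e-12)
})

test_that("assay artifacts and depletion are reported", {
  up <- tibble::tibble(time_min = 0:30, a340 = 0.1 + 0.005 * (0:30))
  w <- testthat::capture_warnings(hydrolysis_rate(up))
  expect_true(any(grepl("artifact", w)))
  expect_error(
    simulate_absorbance_trace(nadh_rate = 1e-4, noise_sigma = 0),
    "depleted at t"
  )
  tr <- tibble::tibble(time_min = 0:5, a340 = 0.8 - 0.001 * (0:5))
  expect_error(hydrolysis_rate(tr), ">= 10")
})

test_that("plate processing joins wells to controls", {
  sims <- lapply(c(1e-6, 2e-6), function(v) {
    simulate_absorbance_trace(nadh_rate = v, noise_sigma = 0, seed = 7)
  })
  plate <- dplyr::bind_rows(
    dplyr::mutate(sims[[1]]$traces[sims[[1]]$traces$trace == "reaction", ],
                  well = "A1"),
    dplyr::mutate(sims[[2]]$traces[sims[[2]]$traces$trace == "reaction", ],
                  well = "A2"),
    dplyr::mutate(sims[[1]]$traces[sims[[1]]$traces$trace == "control", ],
                  well = "H1")
  )
  plate_map <- tibble::tibble(
    well = c("A1", "A2", "H1"),
    condition = c("wt", "wt-2x", "blank"),
    enzyme_uM = c(1, 1, NA),
    control_well = c("H1", "H1", NA)
  )
  res <- suppressWarnings(gtpase_plate(plate, plate_map))
  expect_equal(nrow(res), 2L)
  expect_equal(res$nadh_rate_uM_min, c(1, 2), tolerance = 1e-9)
})
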