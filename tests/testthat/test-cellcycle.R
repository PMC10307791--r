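test_that("measure_cell accounts intensities, areas and concentrations additively", {
  img <- matrix(1, 20, 30)             # background 1 outside the cell
  cell <- matrix(0L, 20, 30); cell[6:15, 6:25] <- 1L
  img[cell > 0] <- 3                   # cytoplasm value 3 (conc 2 after bg)
  cl <- matrix(0L, 20, 30); cl[9:12, 14:17] <- 1L
  img[cl > 0] <- 11                    # cluster conc 10 after bg
  m <- measure_cell(img, cell, cl)
  expect_equal(m$total_intensity, m$cluster_intensity + m$cytoplasm_intensity)
  expect_equal(m$total_area, m$cluster_area + m$cytoplasm_area)
  expect_equal(m$cluster_conc, 10)
  expect_equal(m$cytoplasm_conc, 2)
  expect_equal(m$enrichment_factor, 5)

  # no cluster: cluster terms zero, enrichment flagged NA
  m0 <- measure_cell(img, cell)
  expect_equal(m0$cluster_intensity, 0)
  expect_true(is.na(m0$enrichment_factor))
  expect_equal(m0$cytoplasm_conc, mean(img[cell > 0]) - 1)

  bad_cl <- matrix(0L, 20, 30); bad_cl[1, 1] <- 1L
  expect_error(measure_cell(img, cell, bad_cl), "outside")
})

test_that("snapshot generator yields constant fluorescence concentration", {
  sn <- simulate_cell_snapshots(10, seed = 3)
  for (i in c(1, 5, 10)) {
    m <- measure_cell(sn$records$image[[i]], sn$records$cell_mask[[i]],
                      sn$records$cluster_mask[[i]])
    expect_equal(m$cell_conc, sn$truth$concentration, tolerance = 1e-9)
    expect_equal(m$enrichment_factor, sn$truth$enrichment, tolerance = 1e-9)
  }
})

test_that("cluster geometry matches analytic moments and is rotation invariant", {
  # rectangle 20 x 5 px: aspect ratio exactly 4 under unit-square moments
  rect <- matrix(0L, 30, 30); rect[6:10, 6:25] <- 1L
  g <- cluster_geometry(rect, pixel_size = 100)
  expect_equal(g$aspect_ratio, 4, tolerance = 1e-9)
  expect_equal(g$long_axis_um, 4 * sqrt(20^2 / 12) * 0.1, tolerance = 1e-9)

  rot <- t(rect)  # 90 degree rotation
  g2 <- cluster_geometry(rot, pixel_size = 100)
  expect_equal(g2$long_axis_um, g$long_axis_um)
  expect_equal(g2$aspect_ratio, g$aspect_ratio)

  # disc: aspect ratio 1 within discretization
  disc <- matrix(0L, 40, 40)
  disc[(row(disc) - 20)^2 + (col(disc) - 20)^2 <= 100] <- 1L
  expect_equal(cluster_geometry(disc, 100)$aspect_ratio, 1, tolerance = 0.02)

  expect_error(cluster_geometry(matrix(0L, 5, 5), 100), "empty")
})

test_that("axis regression recovers collinear truth exactly and is duplication invariant", {
  sn <- simulate_cell_snapshots(30, slope = 0.1, intercept = 0.3,
                                axis_noise_sd = 0, seed = 7)
  reg <- suppressWarnings(axis_length_regression(sn$records))
  expect_equal(reg$slope, 0.1, tolerance = 1e-9)
  expect_equal(reg$intercept, 0.3, tolerance = 1e-9)

  dup <- dplyr::bind_rows(sn$records[1:10, ], sn$records[1:10, ])
  reg1 <- suppressWarnings(axis_length_regression(sn$records[1:10, ]))
  reg2 <- suppressWarnings(axis_length_regression(dup))
  expect_equal(reg2$slope, reg1$slope)
  expect_equal(reg2$intercept, reg1$intercept)

  flat <- tibble::tibble(long_axis_um = 1:5, cell_length_um = rep(2, 5))
  expect_error(axis_length_regression(flat), "variance")
})

test_that("zero-slope short axes fit near zero over seeds", {
  slopes <- vapply(1:20, function(s) {
    sn <- simulate_cell_snapshots(60, slope = 0, intercept = 0.5,
                                  axis_noise_sd = 0.05, seed = s)
    reg <- axis_length_regression(sn$records)
    reg$slope / reg$slope_se
  }, numeric(1))
  expect_gt(mean(abs(slopes) < 3), 0.9)
})

test_that("division conservation recovers the generator fraction", {
  ev <- simulate_division_event(conservation = 1, asymmetry = 0.5,
                                noise_sigma = 0)
  expect_equal(division_conservation(ev)$conservation_cluster, 100,
               tolerance = 1e-9)

  ev87 <- simulate_division_event(conservation = 0.87, noise_sigma = 0)
  expect_equal(division_conservation(ev87)$conservation_cluster, 87,
               tolerance = 1e-9)

  # all conserved intensity to one daughter
  ev_asym <- simulate_division_event(conservation = 0.8, asymmetry = 1,
                                     noise_sigma = 0)
  post <- ev_asym$frames$post
  d2 <- sum(post$image[post$cluster_mask == 2L])
  expect_equal(d2, 0)
  expect_equal(division_conservation(ev_asym)$conservation_cluster, 80,
               tolerance = 1e-9)

  # disintegration: clusters vanish, total conserved as diffuse signal
  evd <- simulate_division_event(conservation = 0.87, mode = "disintegration",
                                 noise_sigma = 0)
  res <- division_conservation(evd)
  expect_equal(res$conservation_cluster, 0)
  expect_equal(res$conservation_total, 87, tolerance = 1e-6)

  # hand arithmetic: daughters 90 + 84 over mother 200
  expect_equal(100 * (90 + 84) / 200, 87)
})

test_that("cluster counting excludes zero-cluster cells from the mean", {
  res <- count_clusters(c(0L, 1L, 1L, 2L))
  expect_equal(res$mean_clusters, 4 / 3)
  expect_equal(res$n_cells_with_cluster, 3L)
  expect_equal(res$histogram$n_cells, c(1L, 2L, 1L))

  expect_equal(count_clusters(c(1L, 1L, 1L))$mean_clusters, 1)
  expect_true(is.na(count_clusters(c(0L, 0L))$mean_clusters))
})

test_that("constriction colocalization counts matches within tolerance", {
  expect_equal(constriction_colocalization(c(1, 2, 3), c(1, 2, 3))$fraction, 1)
  expect_equal(constriction_colocalization(c(1, 2), c(10, 20))$fraction, 0)
  res <- constriction_colocalization(c(1, 2, 3), c(1.2, 2.9), tolerance_um = 0.5)
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$n_colocalized, 2L)
})

test_that("absolute concentration conversion inverts the mixture identity", {
  out <- absolute_concentrations(mean_cell_conc_uM = 0.2,
                                 enrichment_factor = 12,
                                 cluster_volume_fraction = 0.05)
  f <- 0.05
  expect_equal(f * out$cluster_conc_uM + (1 - f) * out$cytoplasm_conc_uM, 0.2)
  expect_equal(out$cluster_conc_uM / out$cytoplasm_conc_uM, 12)
})
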