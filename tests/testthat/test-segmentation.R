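test_that("connected-component labeling honours 8- vs 4-connectivity", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1
  m[3, 3] <- 1  # diagonal touch
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  expect_equal(max(label_components(matrix(0, 8, 8))), 0L)
  # labels contiguous from 1, deterministic raster order
  m2 <- matrix(0, 8, 8)
  m2[7:8, 7:8] <- 1
  m2[1:2, 1:2] <- 1
  lab <- label_components(m2)
  expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
  expect_equal(lab[1, 1], 1L)  # first raster-order component is label 1
})

test_that("segmentation finds well-separated objects at true positions", {
  cfg <- clean_config(c(96, 96), seed = 5)
  sim <- simulate_condensate_scene(cfg, n_objects = 7)
  mip <- max_intensity_projection(sim$scene, 1)
  lab <- segment_condensates(mip, smooth_sigma = 0)
  cset <- screen_condensates(lab, mip)
  expect_equal(nrow(cset$objects), 7L)
  # centroids within 1 px of truth (pixel-center convention)
  true_r <- sim$truth$centers$y_nm / cfg$pixel_size + 0.5
  true_c <- sim$truth$centers$x_nm / cfg$pixel_size + 0.5
  for (i in seq_len(7)) {
    d <- sqrt((cset$objects$centroid_row - true_r[i])^2 +
              (cset$objects$centroid_col - true_c[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("segmentation is deterministic and degenerate images yield no objects", {
  blank <- matrix(3, 32, 32)
  expect_equal(max(segment_condensates(blank)), 0L)

  cfg <- noisy_config(seed = 9)
  mip <- max_intensity_projection(simulate_condensate_scene(cfg, n_objects = 8)$scene, 1)
  expect_identical(segment_condensates(mip), segment_condensates(mip))
})

test_that("watershed splits touching objects", {
  img <- matrix(0, 40, 40)
  yy <- row(img) - 0.5
  xx <- col(img) - 0.5
  # two discs whose masks merge
  img[(yy - 20)^2 + (xx - 14)^2 <= 36] <- 10
  img[(yy - 20)^2 + (xx - 26)^2 <= 36] <- 10
  merged <- segment_condensates(img, smooth_sigma = 0, refine = "none")
  expect_equal(max(merged), 1L)
  split <- segment_condensates(img, smooth_sigma = 0, refine = "none",
                               watershed = TRUE)
  expect_equal(max(split), 2L)
})

test_that("screening matches brute-force predicate evaluation", {
  # Fixture: objects straddling both thresholds. Background pixels have
  # mean 2, SD 1 -> intensity cut at 2 + 3*1 = 5 on the object mean.
  img <- matrix(rep(c(1, 3), 128), 16, 16)  # bg mean 2, pop SD 1
  lab <- matrix(0L, 16, 16)
  paint <- function(lab, img, label, px, value) {
    lab[px] <- label
    img[px] <- value
    list(lab = lab, img = img)
  }
  specs <- list(
    list(px = 1:9,           value = 10),   # area 9, bright -> keep
    list(px = 17:24,         value = 10),   # area 8, bright -> drop (size)
    list(px = 33:41,         value = 5),    # area 9, mean exactly at cut -> keep
    list(px = 49:57,         value = 4.9),  # area 9, below cut -> drop
    list(px = 65:76,         value = 50)    # area 12, bright -> keep
  )
  for (i in seq_along(specs)) {
    r <- paint(lab, img, i, specs[[i]]$px, specs[[i]]$value)
    lab <- r$lab; img <- r$img
  }
  # fixed background stats so the thresholds sit exactly on the boundaries
  bg <- tibble::tibble(mean = 2, stdev = 1, n_pixels = 100L)
  cset <- screen_condensates(lab, img, bg = bg, min_area_px = 9, k = 3)

  # independent brute-force evaluation of the same predicate
  survivors <- Filter(function(i) {
    px <- specs[[i]]$px
    length(px) >= 9 && mean(img[px]) >= bg$mean + 3 * bg$stdev
  }, seq_along(specs))
  expect_equal(nrow(cset$objects), length(survivors))
  expect_equal(cset$objects$area_px,
               vapply(survivors, function(i) length(specs[[i]]$px), integer(1)))
  # relabeled contiguously from 1
  expect_equal(cset$objects$label, seq_along(survivors))
  # boundary conventions: exactly-at-threshold objects are retained,
  # strictly-below ones removed
  expect_true(all(c(1L, 3L, 5L) %in% survivors))
  expect_false(any(c(2L, 4L) %in% survivors))
})

test_that("screening is idempotent", {
  cfg <- noisy_config(seed = 4)
  sim <- simulate_condensate_scene(cfg, n_objects = 10)
  mip <- max_intensity_projection(sim$scene, 1)
  bg0 <- estimate_background(mip, segment_condensates(mip))
  cs1 <- screen_condensates(segment_condensates(mip), mip, bg = bg0)
  cs2 <- screen_condensates(cs1$label_map, mip, bg = bg0)
  expect_identical(cs1$label_map, cs2$label_map)
  expect_equal(cs1$objects$area_px, cs2$objects$area_px)
  expect_equal(cs1$objects$mean_intensity, cs2$objects$mean_intensity)
})
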