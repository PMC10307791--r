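test_that("condensate scenes are deterministic under the seed", {
  cfg <- noisy_config(seed = 123)
  a <- simulate_condensate_scene(cfg, n_objects = 8)
  b <- simulate_condensate_scene(cfg, n_objects = 8)
  expect_identical(a$scene$data, b$scene$data)
  expect_identical(a$label_map, b$label_map)
  expect_equal(a$truth$true_separation_factor, b$truth$true_separation_factor)
  c <- simulate_condensate_scene(scene_config(c(128, 128), seed = 124),
                                 n_objects = 8)
  expect_false(identical(a$scene$data, c$scene$data))
})

test_that("uniform client (P = 1, no bleedthrough) gives enrichment 1", {
  sim <- simulate_condensate_scene(clean_config(seed = 2), n_objects = 5,
                                   client_partition = 1, bleedthrough = 0)
  enr <- client_enrichment(get_plane(sim$scene, 2, 1), sim$label_map)
  expect_equal(enr$raw_enrichment, 1)
})

test_that("truth separation factor equals direct summation of the object model", {
  sim <- simulate_condensate_scene(clean_config(seed = 6), n_objects = 4)
  ch1 <- get_plane(sim$scene, 1, 1)  # clean scene: rendered == model
  inside <- sum(ch1[sim$label_map > 0])
  expect_equal(sim$truth$true_separation_factor, 100 * inside / sum(ch1))
})

test_that("PSF blur conserves total integrated intensity on noiseless scenes", {
  base <- scene_config(c(96, 96), psf_sigma = 0, poisson_scale = 0,
                       read_sigma = 0, seed = 31)
  blur <- scene_config(c(96, 96), psf_sigma = 400, poisson_scale = 0,
                       read_sigma = 0, seed = 31)
  s0 <- simulate_condensate_scene(base, n_objects = 6)
  s1 <- simulate_condensate_scene(blur, n_objects = 6)
  for (ch in 1:2) {
    expect_equal(sum(s1$scene$data[, , ch, 1]), sum(s0$scene$data[, , ch, 1]),
                 tolerance = 1e-9)
  }
})

test_that("bleedthrough adds a beta-scaled copy of the scaffold channel", {
  s0 <- simulate_condensate_scene(clean_config(seed = 8), n_objects = 5,
                                  bleedthrough = 0)
  s1 <- simulate_condensate_scene(clean_config(seed = 8), n_objects = 5,
                                  bleedthrough = 0.2)
  delta <- get_plane(s1$scene, 2, 1) - get_plane(s0$scene, 2, 1)
  expect_equal(delta, 0.2 * get_plane(s0$scene, 1, 1), tolerance = 1e-12)
})

test_that("overcrowded placement fails with a clear error", {
  cfg <- clean_config(c(32, 32), seed = 1)
  expect_error(
    simulate_condensate_scene(cfg, n_objects = 200, radius_nm = c(500, 600),
                              max_attempts = 50),
    "attempts"
  )
})

test_that("z-stacks carry spheres across slices and project consistently", {
  cfg <- scene_config(c(64, 64, 12), psf_sigma = 0, poisson_scale = 0,
                      read_sigma = 0, seed = 3)
  sim <- simulate_condensate_scene(cfg, n_objects = 3,
                                   radius_nm = c(500, 700))
  expect_equal(n_slices(sim$scene), 12L)
  mip <- max_intensity_projection(sim$scene, 1)
  expect_equal(sum(mip[sim$label_map > 0]),
               sim$truth$true_separation_factor / 100 * sum(mip))
})

test_that("filament bundling raises image CV and is inert for one path", {
  cfg <- clean_config(c(128, 128), seed = 21)
  f0 <- simulate_filament_scene(cfg, bundling = 0)
  f1 <- simulate_filament_scene(cfg, bundling = 1)
  expect_gt(image_cv(get_plane(f1$scene))$cv, image_cv(get_plane(f0$scene))$cv)
  # fixed total intensity (same seed, same number of deposits)
  expect_equal(sum(f1$scene$data), sum(f0$scene$data), tolerance = 1e-9)

  s0 <- simulate_filament_scene(clean_config(c(64, 64), seed = 4), n_paths = 1,
                                bundling = 0)
  s1 <- simulate_filament_scene(clean_config(c(64, 64), seed = 4), n_paths = 1,
                                bundling = 1)
  expect_identical(s0$scene$data, s1$scene$data)

  expect_error(simulate_filament_scene(cfg, bundling = 1.2), "bundling")
})

test_that("mean filament CV is monotone non-decreasing in bundling", {
  mean_cv <- function(b) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_filament_scene(clean_config(c(96, 96), seed = s),
                                     n_paths = 20, bundling = b)
      image_cv(get_plane(sim$scene))$cv
    }, numeric(1)))
  }
  cvs <- vapply(c(0, 0.5, 1), mean_cv, numeric(1))
  expect_true(all(diff(cvs) >= 0))
})
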