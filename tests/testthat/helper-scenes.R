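# Shared fixture builders. "Clean" configs disable PSF blur and noise so
# estimators can be checked against ground truth exactly.

clean_config <- function(shape = c(96, 96), seed = 1, pixel_size = 207.6) {
  scene_config(shape, pixel_size = pixel_size, psf_sigma = 0,
               poisson_scale = 0, read_sigma = 0, seed = seed)
}

noisy_config <- function(shape = c(128, 128), seed = 1) {
  scene_config(shape, seed = seed)  # package defaults: PSF + Poisson + read
}

# A tiny deterministic two-phase image: `n_in` labeled pixels of value
# `dense` in a `ny` x `nx` field of value `dilute`.
toy_two_phase <- function(ny = 4, nx = 4, n_in = 4, dense = 10, dilute = 1) {
  img <- matrix(dilute, ny, nx)
  lab <- matrix(0L, ny, nx)
  idx <- seq_len(n_in)
  img[idx] <- dense
  lab[idx] <- 1L
  list(image = img, label = lab)
}
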