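#' Acquisition configuration for synthetic scenes
#'
#' Bundles the imaging parameters shared by all synthetic-scene generators:
#' field size, pixel calibration, point-spread-function width and the camera
#' noise model (Poisson photon noise followed by additive Gaussian read
#' noise). The same config with the same seed always produces bit-identical
#' output.
#'
#' @param image_shape Integer vector of pixels per axis: `c(ny, nx)` for a 2-d
#'   field or `c(ny, nx, nz)` for a z-stack. All dimensions must be >= 8.
#' @param pixel_size Pixel edge length in nm. The default, 207.6 nm, matches a
#'   106.3 um field of view sampled at 512 x 512.
#' @param psf_sigma Standard deviation of the isotropic Gaussian PSF in nm;
#'   0 disables blurring.
#' @param poisson_scale Photons per intensity unit for the shot-noise stage;
#'   0 disables Poisson noise.
#' @param read_sigma Gaussian read-noise standard deviation in intensity
#'   units; 0 disables read noise.
#' @param seed Integer seed; fully determines the generated arrays.
#'
#' @return A list of class `scene_config`.
#' @export
#' @examples
#' cfg <- scene_config(c(64, 64), psf_sigma = 0, poisson_scale = 0,
#'                     read_sigma = 0, seed = 1)
scene_config <- function(image_shape = c(256L, 256L),
                         pixel_size = 207.6,
                         psf_sigma = 100,
                         poisson_scale = 50,
                         read_sigma = 0.5,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (!length(image_shape) %in% c(2L, 3L)) {
    stop("`image_shape` must have 2 or 3 elements", call. = FALSE)
  }
  if (any(image_shape < 8L)) stop("all image dimensions must be >= 8 px", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (psf_sigma < 0) stop("`psf_sigma` must be >= 0", call. = FALSE)
  if (poisson_scale < 0 || read_sigma < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  structure(
    list(image_shape = image_shape, pixel_size = pixel_size,
         psf_sigma = psf_sigma,
         noise = list(poisson_scale = poisson_scale, read_sigma = read_sigma),
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Gaussian PSF blur with a kernel normalized to sum 1 (circular boundary),
# so noiseless scenes conserve total integrated intensity exactly.
apply_psf <- function(img, psf_sigma_nm, pixel_size_nm) {
  if (psf_sigma_nm <= 0) return(img)
  sigma_px <- psf_sigma_nm / pixel_size_nm
  EBImage::gblur(img, sigma = sigma_px)
}

# Camera model: Poisson photon noise on the (blurred) intensity, then
# additive Gaussian read noise, clamped at zero. Consumes the current RNG
# stream; callers are responsible for seeding.
add_camera_noise <- function(img, poisson_scale, read_sigma) {
  out <- img
  if (poisson_scale > 0) {
    out[] <- stats::rpois(length(out), lambda = poisson_scale * pmax(out, 0)) /
      poisson_scale
  }
  if (read_sigma > 0) {
    out[] <- out + stats::rnorm(length(out), 0, read_sigma)
  }
  pmax(out, 0)
}

# Render one channel of a (possibly 3-d) noiseless object model into a
# measured image: per-slice PSF blur then scene-wide noise.
render_channel <- function(stack, config) {
  nz <- dim(stack)[3L]
  for (z in seq_len(nz)) {
    stack[, , z] <- apply_psf(stack[, , z], config$psf_sigma, config$pixel_size)
  }
  stack[] <- add_camera_noise(stack, config$noise$poisson_scale,
                              config$noise$read_sigma)
  stack
}
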