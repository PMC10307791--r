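#' Simulate a two-channel condensate scene with known ground truth
#'
#' Renders a two-phase image: spherical dense-phase objects (condensates) of
#' intensity `dense_intensity` over a dilute background of
#' `dilute_intensity` in channel 1 (the scaffold protein), and a client
#' channel in which the client partitions into the dense phase with ratio
#' `client_partition`, plus an optional bleedthrough fraction of channel 1.
#' Both channels are PSF-blurred and noised according to `config`. All
#' exported truth values are computed from the noiseless, pre-blur object
#' model, never re-estimated from the rendered image.
#'
#' @param config A [scene_config()].
#' @param n_objects Number of condensates to place.
#' @param radius_nm Length-2 range (or single value) of condensate radii in
#'   nm; radii must be at least 2 px after calibration.
#' @param dense_intensity,dilute_intensity Channel-1 intensities of the dense
#'   and dilute phase (`dense > dilute >= 0`).
#' @param client_partition Client dense/dilute concentration ratio (> 0).
#' @param client_dilute Client intensity in the dilute phase.
#' @param bleedthrough Fraction of channel 1 added to channel 2, in `[0, 1)`.
#' @param max_attempts Rejection-sampling cap for non-overlapping placement.
#'
#' @return A list with elements
#'   * `scene`: two-channel [image_scene()] (`"condensate"`, `"client"`);
#'   * `truth`: list of class `condensate_scene_truth` with the object table
#'     (`centers` tibble in nm), intensities, partition, bleedthrough,
#'     `true_separation_factor` (percent) and `true_raw_enrichment`;
#'   * `label_map`: integer matrix labeling the projected noiseless objects.
#' @export
#' @examples
#' cfg <- scene_config(c(64, 64), psf_sigma = 0, poisson_scale = 0,
#'                     read_sigma = 0, seed = 7)
#' sim <- simulate_condensate_scene(cfg, n_objects = 3)
#' sim$truth$true_separation_factor
simulate_condensate_scene <- function(config,
                                      n_objects = 25,
                                      radius_nm = c(500, 1100),
                                      dense_intensity = 10,
                                      dilute_intensity = 1,
                                      client_partition = 5,
                                      client_dilute = 1,
                                      bleedthrough = 0,
                                      max_attempts = 10000) {
  stopifnot(inherits(config, "scene_config"))
  if (dense_intensity <= dilute_intensity || dilute_intensity < 0) {
    stop("need dense_intensity > dilute_intensity >= 0", call. = FALSE)
  }
  if (client_partition <= 0) stop("`client_partition` must be > 0", call. = FALSE)
  if (bleedthrough < 0 || bleedthrough >= 1) {
    stop("`bleedthrough` must be in [0, 1)", call. = FALSE)
  }
  if (length(radius_nm) == 1L) radius_nm <- rep(radius_nm, 2L)
  px <- config$pixel_size
  if (min(radius_nm) < 2 * px) {
    stop("radii must be >= 2 px after calibration", call. = FALSE)
  }
  shp <- config$image_shape
  ny <- shp[1L]; nx <- shp[2L]
  nz <- if (length(shp) == 3L) shp[3L] else 1L
  is3d <- nz > 1L

  set.seed(config$seed)
  # Sequential rejection sampling: object i consumes RNG draws before object
  # i + 1, so adding objects never perturbs earlier ones.
  centers <- matrix(NA_real_, n_objects, 3L)  # y, x, z in nm
  radii <- numeric(n_objects)
  for (i in seq_len(n_objects)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      r <- stats::runif(1, radius_nm[1L], radius_nm[2L])
      margin <- r + px
      cy <- stats::runif(1, margin, ny * px - margin)
      cx <- stats::runif(1, margin, nx * px - margin)
      cz <- if (is3d) stats::runif(1, margin, nz * px - margin) else 0.5 * px
      if (i > 1L) {
        dd <- sqrt((centers[seq_len(i - 1L), 1L] - cy)^2 +
                   (centers[seq_len(i - 1L), 2L] - cx)^2 +
                   (if (is3d) (centers[seq_len(i - 1L), 3L] - cz)^2 else 0))
        if (any(dd < radii[seq_len(i - 1L)] + r + px)) next
      }
      centers[i, ] <- c(cy, cx, cz)
      radii[i] <- r
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(
        "could not place object %d of %d without overlap after %d attempts; reduce n_objects or radii",
        i, n_objects, max_attempts), call. = FALSE)
    }
  }

  # Noiseless pre-blur object model. Pixel centers at (i - 0.5) * px.
  yy <- (seq_len(ny) - 0.5) * px
  xx <- (seq_len(nx) - 0.5) * px
  obj_label <- array(0L, dim = c(ny, nx, nz))
  for (z in seq_len(nz)) {
    zc <- (z - 0.5) * px
    for (i in seq_len(n_objects)) {
      r2 <- radii[i]^2 - (if (is3d) (zc - centers[i, 3L])^2 else 0)
      if (r2 <= 0) next
      dy2 <- (yy - centers[i, 1L])^2
      dx2 <- (xx - centers[i, 2L])^2
      inside <- outer(dy2, dx2, `+`) <= r2
      obj_label[, , z][inside] <- i
    }
  }
  ch1 <- array(dilute_intensity, dim = c(ny, nx, nz))
  ch1[obj_label > 0L] <- dense_intensity
  ch2 <- array(client_dilute, dim = c(ny, nx, nz))
  ch2[obj_label > 0L] <- client_partition * client_dilute
  ch2 <- ch2 + bleedthrough * ch1

  # Truth from the noiseless model, on the 2-d projection the downstream
  # statistics use.
  proj_label <- apply(obj_label, c(1, 2), max)
  ch1_mip <- apply(ch1, c(1, 2), max)
  tsf <- 100 * sum(ch1_mip[proj_label > 0L]) / sum(ch1_mip)
  ch2_slice <- ch2[, , if (is3d) which.max(apply(obj_label > 0, 3, sum)) else 1L]
  lab_slice <- obj_label[, , if (is3d) which.max(apply(obj_label > 0, 3, sum)) else 1L]
  true_enr <- mean(ch2_slice[lab_slice > 0L]) / mean(ch2_slice[lab_slice == 0L])

  rendered <- array(0, dim = c(ny, nx, 2L, nz))
  rendered[, , 1L, ] <- render_channel(ch1, config)
  rendered[, , 2L, ] <- render_channel(ch2, config)
  scene <- image_scene(rendered, pixel_size = px,
                       channel_names = c("condensate", "client"))

  truth <- structure(list(
    centers = tibble::tibble(y_nm = centers[, 1L], x_nm = centers[, 2L],
                             z_nm = centers[, 3L], radius_nm = radii),
    dense_intensity = dense_intensity,
    dilute_intensity = dilute_intensity,
    client_partition = client_partition,
    client_dilute = client_dilute,
    bleedthrough = bleedthrough,
    true_separation_factor = tsf,
    true_raw_enrichment = true_enr
  ), class = "condensate_scene_truth")

  list(scene = scene, truth = truth,
       label_map = matrix(as.integer(proj_label), ny, nx))
}
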