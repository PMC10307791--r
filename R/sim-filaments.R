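#' Simulate a filament/bundle scene with a tunable bundling parameter
#'
#' Renders `n_paths` smoothed random-walk curves of fixed total integrated
#' intensity each. With probability `bundling` a path is re-drawn along one
#' of `n_centerlines` shared centerlines (plus a small transverse jitter),
#' concentrating signal into fewer, brighter structures. Because total
#' intensity is fixed, the expected image coefficient of variation increases
#' with `bundling` — the same behaviour crowding agents have on filament
#' images, emulated geometrically rather than physically.
#'
#' Bundling is a multi-path property: with `n_paths = 1` the parameter is
#' ignored and the output is identical for every value of `bundling`.
#'
#' @param config A [scene_config()] (2-d shapes only).
#' @param n_paths Number of filaments (>= 1).
#' @param bundling Probability in `[0, 1]` that a path collapses onto a
#'   shared centerline.
#' @param n_centerlines Number of shared centerlines.
#' @param n_steps Steps per path.
#' @param path_intensity Total integrated intensity deposited per path.
#' @param jitter_px Transverse jitter (px) of bundled paths around their
#'   centerline.
#'
#' @return List with `scene` (single-channel [image_scene()]) and `truth`
#'   (list with `bundling`, `n_paths`, `n_centerlines`).
#' @export
simulate_filament_scene <- function(config,
                                    n_paths = 30,
                                    bundling = 0,
                                    n_centerlines = 3,
                                    n_steps = 300,
                                    path_intensity = 100,
                                    jitter_px = 0.75) {
  stopifnot(inherits(config, "scene_config"))
  if (length(config$image_shape) != 2L) {
    stop("filament scenes are 2-d", call. = FALSE)
  }
  if (n_paths < 1L) stop("`n_paths` must be >= 1", call. = FALSE)
  if (bundling < 0 || bundling > 1) stop("`bundling` must be in [0, 1]", call. = FALSE)
  ny <- config$image_shape[1L]
  nx <- config$image_shape[2L]

  set.seed(config$seed)
  walk <- function(n) {
    # Smoothed random walk: unit steps with autocorrelated heading.
    y <- stats::runif(1, 0.15 * ny, 0.85 * ny)
    x <- stats::runif(1, 0.15 * nx, 0.85 * nx)
    theta <- stats::runif(1, 0, 2 * pi)
    dtheta <- stats::rnorm(n - 1L, 0, 0.15)
    th <- theta + c(0, cumsum(dtheta))
    ys <- y + c(0, cumsum(sin(th[-n])))
    xs <- x + c(0, cumsum(cos(th[-n])))
    # Reflect at borders to keep the deposit inside the field.
    refl <- function(v, lim) {
      v <- abs(v)
      m <- v %% (2 * lim)
      ifelse(m > lim, 2 * lim - m, m)
    }
    cbind(pmin(pmax(refl(ys, ny - 1) + 0.5, 1), ny),
          pmin(pmax(refl(xs, nx - 1) + 0.5, 1), nx))
  }

  # Centerlines and bundling assignments are drawn up front so that the same
  # seed yields the same stream regardless of how they are used.
  centerlines <- lapply(seq_len(n_centerlines), function(i) walk(n_steps))
  u <- stats::runif(n_paths)
  which_cl <- sample.int(n_centerlines, n_paths, replace = TRUE)
  use_bundle <- if (n_paths == 1L) rep(FALSE, n_paths) else u < bundling

  img <- matrix(0, ny, nx)
  per_step <- path_intensity / n_steps
  for (i in seq_len(n_paths)) {
    pts <- if (use_bundle[i]) {
      cl <- centerlines[[which_cl[i]]]
      off <- stats::rnorm(2, 0, jitter_px)
      cbind(pmin(pmax(cl[, 1L] + off[1L], 1), ny),
            pmin(pmax(cl[, 2L] + off[2L], 1), nx))
    } else {
      walk(n_steps)
    }
    ri <- pmin(pmax(round(pts[, 1L]), 1L), ny)
    ci <- pmin(pmax(round(pts[, 2L]), 1L), nx)
    lin <- (ci - 1L) * ny + ri
    tab <- tabulate(lin, nbins = ny * nx)
    img <- img + matrix(tab * per_step, ny, nx)
  }

  img <- apply_psf(img, config$psf_sigma, config$pixel_size)
  img <- add_camera_noise(img, config$noise$poisson_scale, config$noise$read_sigma)
  scene <- image_scene(matrix(img, ny, nx), pixel_size = config$pixel_size,
                       channel_names = "filament")
  list(scene = scene,
       truth = list(bundling = bundling, n_paths = n_paths,
                    n_centerlines = n_centerlines))
}
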