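#' Multi-channel image scene
#'
#' An `image_scene` is the unit every image statistic in this package
#' consumes: a numeric intensity array laid out as `(y, x, channel, z)`
#' (channel and z may be singleton), together with its pixel calibration in
#' nanometres and channel labels.
#'
#' @param data Numeric array. Accepted shapes: `(y, x)`, `(y, x, channel)` or
#'   `(y, x, channel, z)`. Intensities must be finite and non-negative.
#' @param pixel_size Pixel edge length in nm.
#' @param channel_names Character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `image_scene`: a list with elements `data`
#'   (4-d array), `pixel_size` and `channel_names`.
#' @export
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' scn <- image_scene(img, pixel_size = 100)
#' dim(scn$data)
image_scene <- function(data, pixel_size, channel_names = NULL) {
  if (!is.numeric(data)) stop("`data` must be a numeric array", call. = FALSE)
  d <- dim(data)
  if (is.null(d)) stop("`data` must have at least 2 dimensions", call. = FALSE)
  if (length(d) == 2L) dim(data) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(data) <- c(d, 1L)
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 2-, 3- or 4-d array (y, x, channel, z)", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(data < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (nm)", call. = FALSE)
  }
  nch <- dim(data)[3L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (length(channel_names) != nch) {
    stop("`channel_names` length must equal the number of channels", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size = as.numeric(pixel_size),
         channel_names = as.character(channel_names)),
    class = "image_scene"
  )
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_scene> %d x %d px, %d channel(s) [%s], %d z-slice(s), %.1f nm/px\n",
    d[1], d[2], d[3], paste(x$channel_names, collapse = ", "), d[4],
    x$pixel_size
  ))
  invisible(x)
}

# Resolve a channel given as index or name to an integer index.
resolve_channel <- function(scene, channel) {
  if (is.character(channel)) {
    idx <- match(channel, scene$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel, call. = FALSE)
    return(idx)
  }
  idx <- as.integer(channel)
  if (idx < 1L || idx > dim(scene$data)[3L]) {
    stop("channel index out of range: ", channel, call. = FALSE)
  }
  idx
}

#' Extract a single 2-d plane from a scene
#'
#' @param scene An [image_scene()].
#' @param channel Channel index or name.
#' @param z Z-slice index (1-based).
#' @return A numeric matrix.
#' @export
get_plane <- function(scene, channel = 1L, z = 1L) {
  stopifnot(inherits(scene, "image_scene"))
  ch <- resolve_channel(scene, channel)
  z <- as.integer(z)
  if (z < 1L || z > dim(scene$data)[4L]) stop("z out of range", call. = FALSE)
  scene$data[, , ch, z]
}

#' Number of z-slices in a scene
#' @param scene An [image_scene()].
#' @return Integer slice count.
#' @export
n_slices <- function(scene) dim(scene$data)[4L]

#' Number of channels in a scene
#' @param scene An [image_scene()].
#' @return Integer channel count.
#' @export
n_channels <- function(scene) dim(scene$data)[3L]
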