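#' Pick the best-focus z-slice of a stack
#'
#' The best-focus slice is the one with the maximum intensity standard
#' deviation (population convention); ties break to the lowest index.
#'
#' @param scene An [image_scene()].
#' @param channel Channel index or name.
#' @return Integer slice index (1-based).
#' @export
best_focus_slice <- function(scene, channel = 1L) {
  stopifnot(inherits(scene, "image_scene"))
  nz <- n_slices(scene)
  if (nz < 1L) stop("empty stack", call. = FALSE)
  sds <- vapply(seq_len(nz), function(z) sd_pop(get_plane(scene, channel, z)),
                numeric(1))
  which.max(sds)  # which.max returns the first maximum: lowest-index tie-break
}

#' Maximum intensity projection over z
#'
#' @param scene An [image_scene()].
#' @param channel Channel index or name.
#' @return 2-d numeric matrix with the per-pixel maximum over all z-slices.
#' @export
max_intensity_projection <- function(scene, channel = 1L) {
  stopifnot(inherits(scene, "image_scene"))
  ch <- resolve_channel(scene, channel)
  if (n_slices(scene) < 1L) stop("empty stack", call. = FALSE)
  apply(scene$data[, , ch, , drop = FALSE], c(1, 2), max)
}

#' Background statistics outside an exclusion mask
#'
#' Mean and population standard deviation over all pixels outside the
#' exclusion mask — the "remaining areas of the field of view". An empty
#' mask yields whole-image statistics.
#'
#' @param image 2-d numeric matrix.
#' @param exclusion_mask Logical or label matrix; pixels with value > 0 /
#'   TRUE are excluded. `NULL` means no exclusion.
#' @param min_pixels Minimum number of background pixels required.
#' @return One-row tibble: `mean`, `stdev`, `n_pixels`.
#' @export
estimate_background <- function(image, exclusion_mask = NULL, min_pixels = 100L) {
  if (is.null(exclusion_mask)) {
    bg <- as.numeric(image)
  } else {
    stopifnot(all(dim(exclusion_mask) == dim(image)))
    bg <- image[!(exclusion_mask > 0)]
  }
  if (length(bg) < min_pixels) {
    stop(sprintf("only %d background pixels left (need >= %d)",
                 length(bg), min_pixels), call. = FALSE)
  }
  tibble::tibble(mean = mean(bg), stdev = sd_pop(bg),
                 n_pixels = length(bg))
}

#' Image coefficient of variation (bundling/heterogeneity metric)
#'
#' CV is the population standard deviation over the mean of the image
#' (typically a maximum intensity projection). When a `reference_cv` is
#' supplied — e.g., the CV of the no-crowder, no-partner condition — the
#' normalized CV is reported alongside.
#'
#' @param image 2-d numeric matrix (or [image_scene()], in which case the
#'   max projection of `channel` is used).
#' @param reference_cv Optional reference CV for normalization.
#' @param channel Channel used when `image` is a scene.
#' @return One-row tibble: `cv`, `normalized_cv` (NA when no reference).
#' @export
image_cv <- function(image, reference_cv = NULL, channel = 1L) {
  if (inherits(image, "image_scene")) {
    image <- max_intensity_projection(image, channel)
  }
  m <- mean(image)
  if (m <= 0) stop("image mean must be > 0 for a CV", call. = FALSE)
  cv <- sd_pop(image) / m
  norm <- if (is.null(reference_cv)) NA_real_ else {
    if (reference_cv <= 0) stop("`reference_cv` must be > 0", call. = FALSE)
    cv / reference_cv
  }
  tibble::tibble(cv = cv, normalized_cv = norm)
}

#' Normalized network intensity of a channel
#'
#' Mean intensity of the maximum intensity projection divided by a reference
#' mean (e.g., the same fluorophore without partner protein or crowder) — a
#' proxy for how much labeled protein has assembled into large structures
#' that sediment into the imaging volume.
#'
#' @param scene An [image_scene()].
#' @param channel Channel index or name.
#' @param reference_mean Positive reference mean intensity.
#' @return One-row tibble: `mean_intensity`, `normalized_intensity`.
#' @export
network_intensity <- function(scene, channel = 1L, reference_mean) {
  if (reference_mean <= 0) stop("`reference_mean` must be > 0", call. = FALSE)
  m <- mean(max_intensity_projection(scene, channel))
  tibble::tibble(mean_intensity = m,
                 normalized_intensity = m / reference_mean)
}
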