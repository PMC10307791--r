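#' Plot a scene channel as a raster
#'
#' @param scene An [image_scene()].
#' @param channel Channel index or name.
#' @param projection Use the max projection (`TRUE`) or slice `z`.
#' @param z Slice when `projection = FALSE`.
#' @return A ggplot.
#' @export
plot_scene <- function(scene, channel = 1L, projection = TRUE, z = 1L) {
  img <- if (projection) max_intensity_projection(scene, channel) else {
    get_plane(scene, channel, z)
  }
  d <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  d$intensity <- as.vector(img)  # expand_grid varies col fastest: row-major
  d$intensity <- img[cbind(d$row, d$col)]
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` visualisations for fitted objects: a `frap_fit` shows the
#' normalized post-bleach points and the fitted exponential; a
#' `frap_aggregate` shows the mean recovery with an SD ribbon and the pooled
#' fit.
#'
#' @param object A `frap_fit` or `frap_aggregate`.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-condenser
NULL

#' @rdname autoplot-condenser
#' @importFrom ggplot2 autoplot
#' @export
autoplot.frap_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(.data$time_min, .data$normalized)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "time after bleach (min)",
                  y = "fluorescence (% of pre-bleach)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      time_min = seq(min(object$data$time_min), max(object$data$time_min),
                     length.out = 200)
    )
    grid$normalized <- object$y0 + object$A * exp(-grid$time_min / object$t)
    p <- p + ggplot2::geom_line(data = grid, colour = "magenta4",
                                linewidth = 0.8) +
      ggplot2::labs(subtitle = sprintf("t½ = %.2f min", object$t_half))
  }
  p
}

#' @rdname autoplot-condenser
#' @export
autoplot.frap_aggregate <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(.data$time_min, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$stdev,
                                      ymax = .data$mean + .data$stdev),
                         fill = "magenta4", alpha = 0.2) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "time after bleach (min)",
                  y = "fluorescence (% of pre-bleach)") +
    ggplot2::theme_minimal()
  if (object$pooled_fit$converged) {
    f <- object$pooled_fit
    grid <- tibble::tibble(
      time_min = seq(min(object$curve$time_min), max(object$curve$time_min),
                     length.out = 200)
    )
    grid$mean <- f$y0 + f$A * exp(-grid$time_min / f$t)
    p <- p + ggplot2::geom_line(data = grid, colour = "magenta4",
                                linewidth = 0.9)
  }
  p
}

#' Plot segmented condensates over the image
#'
#' @param cset A `condensate_set`.
#' @param image Optional intensity image for context (label map alone
#'   otherwise).
#' @return A ggplot.
#' @export
plot_condensates <- function(cset, image = NULL) {
  lab <- cset$label_map
  base <- if (is.null(image)) lab else image
  d <- tibble::tibble(
    row = rep(seq_len(nrow(base)), times = ncol(base)),
    col = rep(seq_len(ncol(base)), each = nrow(base)),
    intensity = as.vector(base),
    labeled = as.vector(lab) > 0
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = cset$objects,
                        ggplot2::aes(.data$centroid_col, .data$centroid_row),
                        colour = "red", shape = 3, size = 2,
                        inherit.aes = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot absorbance traces with the fitted rate window
#'
#' @param traces Long tibble (`trace`, `time_min`, `a340`).
#' @param result Optional one-row result from [hydrolysis_rate()] to mark
#'   the fit window.
#' @return A ggplot.
#' @export
plot_absorbance <- function(traces, result = NULL) {
  p <- ggplot2::ggplot(traces, ggplot2::aes(.data$time_min, .data$a340,
                                            colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "A340") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    p <- p + ggplot2::annotate("rect", xmin = result$t_start,
                               xmax = result$t_end, ymin = -Inf, ymax = Inf,
                               alpha = 0.1, fill = "steelblue")
  }
  p
}
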