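# Internal pixel-labeling helpers shared by the segmenter and the generators.

# Population standard deviation (divisor n). The whole package fixes the
# population convention for image statistics; see the methods vignette.
sd_pop <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Label connected components of a binary mask
#'
#' Labels foreground pixels of a 2-d logical/0-1 mask with 8-connectivity
#' (default) or 4-connectivity. Labels are positive integers, contiguous from
#' 1, assigned in raster (column-major) order of each component's first
#' pixel, so the labeling is deterministic.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  m <- mask != 0 & !is.na(mask)
  out <- matrix(0L, nrow(m), ncol(m))
  idx <- which(m)
  if (length(idx) == 0L) return(out)
  nr <- nrow(m)
  nc <- ncol(m)
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  # Offsets (drow, dcol) covering each undirected neighbor pair once.
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == "8") offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  for (o in offs) {
    r2 <- row_i + o[1L]
    c2 <- col_i + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- m[nb]
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <-
      rbind(pos[idx[ok][hit]], pos[nb[hit]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(g)$membership
  # Relabel so component 1 is the one whose first pixel comes first in
  # raster order.
  first_seen <- comp[!duplicated(comp)]
  relabel <- integer(max(comp))
  relabel[first_seen] <- seq_along(first_seen)
  out[idx] <- relabel[comp]
  out
}

# Per-label summaries of an intensity image: tibble with label, area_px,
# integrated/mean intensity, centroid (pixel-center, 1-based row/col).
label_stats <- function(label_map, image) {
  stopifnot(all(dim(label_map) == dim(image)))
  idx <- which(label_map > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      label = integer(), area_px = integer(),
      integrated_intensity = numeric(), mean_intensity = numeric(),
      sd_intensity = numeric(),
      centroid_row = numeric(), centroid_col = numeric()
    ))
  }
  nr <- nrow(label_map)
  lab <- label_map[idx]
  val <- image[idx]
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  tibble::tibble(label = lab, value = val, row = row_i, col = col_i) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      area_px = dplyr::n(),
      integrated_intensity = sum(.data$value),
      mean_intensity = mean(.data$value),
      sd_intensity = sd_pop(.data$value),
      centroid_row = mean(.data$row),
      centroid_col = mean(.data$col),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$label)
}
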