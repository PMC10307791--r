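#' Simulate single-cell snapshots with size-scaling clusters
#'
#' Generates `n_cells` rod-shaped cells whose cluster long axis scales
#' linearly with cell length (`long_axis = intercept + slope * length +
#' noise`) and whose total background-corrected fluorescence is proportional
#' to cell area (`total = concentration * area`), i.e., constant fluorescence
#' concentration across the cell cycle. Per-cell images and masks are
#' rendered so the measurement operations can be exercised; the generating
#' parameters are exported as truth.
#'
#' @param n_cells Number of cells (>= 2).
#' @param slope Cluster long-axis scaling slope (um of axis per um of
#'   length).
#' @param intercept Long-axis intercept (um).
#' @param concentration Fluorescence concentration kappa (intensity per
#'   pixel of cell area).
#' @param length_range_um Cell lengths are sampled uniformly on this range.
#' @param axis_noise_sd SD of Gaussian noise on the long axis (um).
#' @param enrichment Cluster/cytoplasm fluorescence-concentration ratio used
#'   to paint the images.
#' @param short_axis_um Cluster short axis (um), independent of length.
#' @param cell_width_um Cell width (um).
#' @param pixel_size Pixel size in nm.
#' @param p_no_cluster Probability that a cell lacks a cluster.
#' @param noise_sigma Gaussian image noise SD.
#' @param seed Integer seed.
#'
#' @return List with `records` — a tibble with one row per cell (`cell_id`,
#'   `cell_length_um`, `long_axis_um`, `short_axis_um`, `n_clusters`, and
#'   list-columns `image`, `cell_mask`, `cluster_mask`) — and `truth` (list
#'   with `slope`, `intercept`, `concentration`, `enrichment`).
#' @export
simulate_cell_snapshots <- function(n_cells,
                                    slope = 0.12,
                                    intercept = 0.25,
                                    concentration = 5,
                                    length_range_um = c(3, 9),
                                    axis_noise_sd = 0,
                                    enrichment = 6,
                                    short_axis_um = 0.45,
                                    cell_width_um = 0.8,
                                    pixel_size = 100,
                                    p_no_cluster = 0,
                                    noise_sigma = 0,
                                    seed = 1L) {
  if (n_cells < 2L) stop("`n_cells` must be >= 2", call. = FALSE)
  px_um <- pixel_size / 1000
  set.seed(as.integer(seed))

  lengths <- stats::runif(n_cells, length_range_um[1L], length_range_um[2L])
  axis_noise <- if (axis_noise_sd > 0) stats::rnorm(n_cells, 0, axis_noise_sd) else numeric(n_cells)
  long_axes <- pmax(intercept + slope * lengths + axis_noise, 2 * px_um)
  has_cluster <- stats::runif(n_cells) >= p_no_cluster

  one_cell <- function(i) {
    len_px <- round(lengths[i] / px_um)
    wid_px <- round(cell_width_um / px_um)
    ny <- wid_px + 8L
    nx <- len_px + 8L
    cell_mask <- matrix(0L, ny, nx)
    cell_mask[5L:(4L + wid_px), 5L:(4L + len_px)] <- 1L
    cluster_mask <- matrix(0L, ny, nx)
    if (has_cluster[i]) {
      a <- long_axes[i] / px_um / 2      # semi-axes in px
      b <- short_axis_um / px_um / 2
      cy <- 4 + wid_px / 2
      cx <- 4 + len_px / 2
      yy <- seq_len(ny) - 0.5
      xx <- seq_len(nx) - 0.5
      ell <- outer((yy - cy)^2 / b^2, (xx - cx)^2 / a^2, `+`) <= 1
      cluster_mask[ell & cell_mask > 0L] <- 1L
    }
    area <- sum(cell_mask > 0L)
    cl_area <- sum(cluster_mask > 0L)
    # Paint cytoplasm u and cluster e*u so that total = kappa * area.
    u <- concentration * area / (area - cl_area + enrichment * cl_area)
    img <- matrix(0, ny, nx)
    img[cell_mask > 0L] <- u
    img[cluster_mask > 0L] <- enrichment * u
    if (noise_sigma > 0) img <- pmax(img + stats::rnorm(length(img), 0, noise_sigma), 0)
    list(image = img, cell_mask = cell_mask, cluster_mask = cluster_mask)
  }
  cells <- lapply(seq_len(n_cells), one_cell)

  records <- tibble::tibble(
    cell_id = seq_len(n_cells),
    cell_length_um = lengths,
    long_axis_um = ifelse(has_cluster, long_axes, NA_real_),
    short_axis_um = ifelse(has_cluster, short_axis_um, NA_real_),
    n_clusters = as.integer(has_cluster),
    image = lapply(cells, `[[`, "image"),
    cell_mask = lapply(cells, `[[`, "cell_mask"),
    cluster_mask = lapply(cells, `[[`, "cluster_mask")
  )
  list(records = records,
       truth = list(slope = slope, intercept = intercept,
                    concentration = concentration, enrichment = enrichment))
}
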