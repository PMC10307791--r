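#' Per-cell cluster and cytoplasm measurements
#'
#' Background-corrected intensities, areas, fluorescence concentrations
#' (intensity / area, a proxy for protein concentration) and the enrichment
#' factor (cluster concentration / cytoplasm concentration) for one cell.
#' The background is a per-image scalar: the mean intensity outside all cell
#' masks, unless supplied.
#'
#' @param image 2-d intensity matrix.
#' @param cell_mask Label/logical matrix of the cell (pixels > 0).
#' @param cluster_mask Label/logical matrix of the cluster(s); must be a
#'   subset of the cell mask.
#' @param background Scalar background level; `NULL` estimates it as the
#'   mean outside the cell mask.
#' @return One-row tibble: intensities (`total_`, `cluster_`,
#'   `cytoplasm_intensity`), areas (`_area` in px), concentrations
#'   (`cell_conc`, `cluster_conc`, `cytoplasm_conc`), `enrichment_factor`
#'   (NA with zero-cluster cells), `n_clusters`, `background`.
#' @export
measure_cell <- function(image, cell_mask, cluster_mask = NULL,
                         background = NULL) {
  stopifnot(all(dim(cell_mask) == dim(image)))
  if (is.null(cluster_mask)) cluster_mask <- matrix(0L, nrow(image), ncol(image))
  stopifnot(all(dim(cluster_mask) == dim(image)))
  if (any(cluster_mask > 0 & !(cell_mask > 0))) {
    stop("cluster pixels outside the cell mask", call. = FALSE)
  }
  if (is.null(background)) {
    out <- image[!(cell_mask > 0)]
    background <- if (length(out) > 0L) mean(out) else 0
  }
  in_cell <- cell_mask > 0
  in_cluster <- cluster_mask > 0
  total_area <- sum(in_cell)
  cluster_area <- sum(in_cluster)
  cyto_area <- total_area - cluster_area
  total_int <- sum(image[in_cell]) - background * total_area
  cluster_int <- sum(image[in_cluster]) - background * cluster_area
  cyto_int <- total_int - cluster_int
  cluster_conc <- if (cluster_area > 0L) cluster_int / cluster_area else NA_real_
  cyto_conc <- if (cyto_area > 0L) cyto_int / cyto_area else NA_real_
  tibble::tibble(
    total_intensity = total_int,
    cluster_intensity = cluster_int,
    cytoplasm_intensity = cyto_int,
    total_area = total_area,
    cluster_area = cluster_area,
    cytoplasm_area = cyto_area,
    cell_conc = total_int / total_area,
    cluster_conc = cluster_conc,
    cytoplasm_conc = cyto_conc,
    enrichment_factor = if (cluster_area > 0L && !is.na(cyto_conc) &&
                            cyto_conc > 0) cluster_conc / cyto_conc else NA_real_,
    n_clusters = length(unique(cluster_mask[in_cluster])),
    background = background
  )
}

#' Cluster geometry from mask moments
#'
#' Long and short axes are the major and minor axis lengths of the
#' ellipse with the same (intensity-unweighted) second central moments as the
#' mask: `4 * sqrt(eigenvalue)` of the pixel-coordinate covariance matrix,
#' converted to micrometres.
#'
#' @param mask Logical/label matrix of a single cluster (pixels > 0).
#' @param pixel_size Pixel size in nm.
#' @return One-row tibble: `long_axis_um`, `short_axis_um`, `aspect_ratio`
#'   (>= 1), `area_px`.
#' @export
cluster_geometry <- function(mask, pixel_size) {
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("empty cluster mask", call. = FALSE)
  nr <- nrow(mask)
  ys <- ((idx - 1L) %% nr) + 1L
  xs <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  cov_m <- if (n > 1L) {
    stats::cov(cbind(ys, xs)) * (n - 1) / n  # population moments
  } else {
    matrix(0, 2, 2)
  }
  ev <- sort(pmax(eigen(cov_m, symmetric = TRUE)$values, 0), decreasing = TRUE)
  # + 1/12: each pixel is a unit square, not a point mass.
  axes_px <- 4 * sqrt(ev + 1 / 12)
  um <- pixel_size / 1000
  tibble::tibble(
    long_axis_um = axes_px[1L] * um,
    short_axis_um = axes_px[2L] * um,
    aspect_ratio = axes_px[1L] / axes_px[2L],
    area_px = n
  )
}

#' Linear size scaling of cluster axes with cell length
#'
#' Ordinary least-squares regression of a cluster-axis column against cell
#' length over a set of cell records — the size-scaling analysis that asks
#' whether cluster dimensions grow with the cell cycle.
#'
#' @param records Data frame with cell measurements; rows with NA axis are
#'   dropped.
#' @param axis Column name (string) of the axis to regress, default
#'   `"long_axis_um"`.
#' @param length_col Column name of the cell length, default
#'   `"cell_length_um"`.
#' @return One-row tibble: `axis`, `slope`, `intercept`, `r_squared`, `n`,
#'   `slope_se`.
#' @export
axis_length_regression <- function(records, axis = "long_axis_um",
                                   length_col = "cell_length_um") {
  d <- records[!is.na(records[[axis]]), c(axis, length_col)]
  if (nrow(d) < 3L) stop("need >= 3 cells with a measured axis", call. = FALSE)
  if (sd_pop(d[[length_col]]) == 0) {
    stop("zero variance in cell length", call. = FALSE)
  }
  fit <- stats::lm(d[[axis]] ~ d[[length_col]])
  s <- summary(fit)
  tibble::tibble(
    axis = axis,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = s$r.squared,
    n = nrow(d),
    slope_se = s$coefficients[2L, 2L]
  )
}

#' Intensity conservation across a cell division
#'
#' For a division event (one pre-division mother frame, one post-division
#' frame with two daughters), computes the summed background-corrected
#' daughter cluster intensity as a percentage of the mother's cluster
#' intensity (`conservation_cluster`) and the same statistic for total
#' cellular intensity (`conservation_total`). A cluster that undergoes
#' fission conserves its cluster intensity; a cluster that disintegrates
#' yields 0% cluster conservation while the total is conserved as diffuse
#' signal.
#'
#' @param event A `division_event` (from [simulate_division_event()] or
#'   assembled with the same structure: `frames$pre` / `frames$post`, each
#'   with `image`, `cell_mask`, `cluster_mask`).
#' @return One-row tibble: `conservation_cluster` (percent; NA when the
#'   mother has no cluster signal), `conservation_total` (percent),
#'   `mother_cluster_intensity`, `daughter_cluster_intensity`.
#' @export
division_conservation <- function(event) {
  pre <- event$frames$pre
  post <- event$frames$post
  frame_sums <- function(fr) {
    bg <- mean(fr$image[fr$cell_mask == 0L])
    cl_idx <- fr$cluster_mask > 0L
    list(
      cluster = sum(fr$image[cl_idx]) - bg * sum(cl_idx),
      total = sum(fr$image[fr$cell_mask > 0L]) - bg * sum(fr$cell_mask > 0L)
    )
  }
  m <- frame_sums(pre)
  d <- frame_sums(post)
  cons_cluster <- if (m$cluster > 0) 100 * d$cluster / m$cluster else NA_real_
  tibble::tibble(
    conservation_cluster = cons_cluster,
    conservation_total = 100 * d$total / m$total,
    mother_cluster_intensity = m$cluster,
    daughter_cluster_intensity = d$cluster
  )
}

#' Cluster counts per cell
#'
#' Histogram of clusters per cell and the mean count over cells that have at
#' least one cluster (cells without clusters are excluded from the mean, not
#' from the histogram).
#'
#' @param counts Integer vector of per-cell cluster counts, or a data frame
#'   with an `n_clusters` column (e.g. the records from
#'   [simulate_cell_snapshots()]).
#' @return List: `histogram` (tibble `n_clusters`, `n_cells`),
#'   `mean_clusters` (NA when no cell has a cluster), `n_cells`,
#'   `n_cells_with_cluster`.
#' @export
count_clusters <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$n_clusters
  counts <- as.integer(counts)
  hist <- tibble::tibble(n_clusters = sort(unique(counts))) |>
    dplyr::mutate(n_cells = vapply(.data$n_clusters,
                                   function(k) sum(counts == k), integer(1)))
  with_cluster <- counts[counts >= 1L]
  list(
    histogram = hist,
    mean_clusters = if (length(with_cluster) > 0L) mean(with_cluster) else NA_real_,
    n_cells = length(counts),
    n_cells_with_cluster = length(with_cluster)
  )
}

#' Fraction of division constrictions colocalizing with a cluster
#'
#' A constriction colocalizes when some cluster centroid lies within
#' `tolerance_um` of it along the cell axis.
#'
#' @param constrictions_um Positions of constrictions along the cell axis
#'   (um).
#' @param centroids_um Positions of cluster centroids (um).
#' @param tolerance_um Colocalization tolerance (default 0.5 um).
#' @return One-row tibble: `fraction`, `n_colocalized`, `n_constrictions`.
#' @export
constriction_colocalization <- function(constrictions_um, centroids_um,
                                        tolerance_um = 0.5) {
  if (length(constrictions_um) == 0L) {
    return(tibble::tibble(fraction = NA_real_, n_colocalized = 0L,
                          n_constrictions = 0L))
  }
  hit <- vapply(constrictions_um, function(p) {
    length(centroids_um) > 0L && min(abs(centroids_um - p)) <= tolerance_um
  }, logical(1))
  tibble::tibble(fraction = mean(hit), n_colocalized = sum(hit),
                 n_constrictions = length(hit))
}

#' Convert an enrichment factor into absolute concentrations
#'
#' Given an estimated mean cellular concentration and the measured cluster /
#' cytoplasm partitioning (enrichment factor and volume fractions), returns
#' the implied absolute cluster and cytoplasm concentrations. The volume
#' fraction of the cluster must be supplied by the user; it is not derivable
#' from 2-d image data alone.
#'
#' @param mean_cell_conc_uM Mean cellular concentration (uM).
#' @param enrichment_factor Cluster/cytoplasm concentration ratio.
#' @param cluster_volume_fraction Fraction of cell volume in the cluster.
#' @return One-row tibble: `cluster_conc_uM`, `cytoplasm_conc_uM`.
#' @export
absolute_concentrations <- function(mean_cell_conc_uM, enrichment_factor,
                                    cluster_volume_fraction) {
  if (cluster_volume_fraction <= 0 || cluster_volume_fraction >= 1) {
    stop("`cluster_volume_fraction` must be in (0, 1)", call. = FALSE)
  }
  # c_mean = f * c_cluster + (1 - f) * c_cyto, c_cluster = E * c_cyto
  f <- cluster_volume_fraction
  c_cyto <- mean_cell_conc_uM / (f * enrichment_factor + (1 - f))
  tibble::tibble(cluster_conc_uM = enrichment_factor * c_cyto,
                 cytoplasm_conc_uM = c_cyto)
}
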