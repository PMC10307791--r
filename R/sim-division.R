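#' Simulate a cell-division event with cluster fission or disintegration
#'
#' Builds a two-frame time-lapse of a rod-shaped mother cell carrying a
#' single fluorescent cluster at midcell, followed by the two daughters after
#' division. In `"fission"` mode the mother cluster's background-corrected
#' integrated intensity M is split between daughter clusters as
#' `conservation * asymmetry * M` and `conservation * (1 - asymmetry) * M`.
#' In `"disintegration"` mode the daughters carry no cluster and their
#' diffuse signal is raised so that their summed background-corrected total
#' equals `conservation` times the mother's total.
#'
#' @param conservation Fraction of mother (cluster or total) intensity
#'   present in the daughters, in `[0, 1]`.
#' @param asymmetry Fraction of the conserved cluster intensity received by
#'   daughter 1, in `[0, 1]` (fission mode only).
#' @param mode `"fission"` or `"disintegration"`.
#' @param cell_length_um,cell_width_um Mother geometry; the mother must be
#'   long enough to split into two daughters of at least
#'   `min_daughter_um` each.
#' @param min_daughter_um Minimum daughter length.
#' @param cluster_radius_um Cluster radius.
#' @param pixel_size Pixel size in nm.
#' @param diffuse_intensity Per-pixel diffuse signal inside cells.
#' @param cluster_intensity Background-corrected integrated cluster
#'   intensity of the mother (M).
#' @param background Per-pixel background outside cells.
#' @param noise_sigma Gaussian noise SD.
#' @param seed Integer seed.
#'
#' @return List of class `division_event`: `frames` (named list `pre`,
#'   `post`, each with `image`, `cell_mask`, `cluster_mask` label matrices)
#'   and `truth` (list of class `division_truth`).
#' @export
simulate_division_event <- function(conservation = 0.87,
                                    asymmetry = 0.5,
                                    mode = c("fission", "disintegration"),
                                    cell_length_um = 6,
                                    cell_width_um = 0.8,
                                    min_daughter_um = 1.5,
                                    cluster_radius_um = 0.35,
                                    pixel_size = 100,
                                    diffuse_intensity = 2,
                                    cluster_intensity = 500,
                                    background = 1,
                                    noise_sigma = 0,
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (conservation < 0 || conservation > 1) stop("`conservation` in [0,1]", call. = FALSE)
  if (asymmetry < 0 || asymmetry > 1) stop("`asymmetry` in [0,1]", call. = FALSE)
  if (cell_length_um / 2 < min_daughter_um) {
    stop("mother too short to split into two daughters of at least ",
         min_daughter_um, " um", call. = FALSE)
  }
  px_um <- pixel_size / 1000  # um per px
  len_px <- round(cell_length_um / px_um)
  wid_px <- round(cell_width_um / px_um)
  rad_px <- cluster_radius_um / px_um
  ny <- wid_px + 10L
  nx <- len_px + 10L

  blank <- function() matrix(0L, ny, nx)
  rows <- 6L:(5L + wid_px)
  cell_cols <- function(from, to) (5L + from):(5L + to)

  disc <- function(cy, cx) {
    yy <- seq_len(ny) - 0.5
    xx <- seq_len(nx) - 0.5
    outer((yy - cy)^2, (xx - cx)^2, `+`) <= rad_px^2
  }

  set.seed(as.integer(seed))
  add_noise <- function(img) {
    if (noise_sigma > 0) img <- img + stats::rnorm(length(img), 0, noise_sigma)
    pmax(img, 0)
  }

  make_frame <- function(cell_spans, clusters) {
    cell_mask <- blank()
    for (i in seq_along(cell_spans)) {
      cell_mask[rows, cell_cols(cell_spans[[i]][1L], cell_spans[[i]][2L])] <- i
    }
    cluster_mask <- blank()
    img <- matrix(background, ny, nx)
    img[cell_mask > 0L] <- background + diffuse_intensity
    for (i in seq_along(clusters)) {
      cl <- clusters[[i]]
      if (cl$intensity <= 0) next
      d <- disc(cl$cy, cl$cx) & cell_mask > 0L
      cluster_mask[d] <- i
      # The cluster region carries the cluster signal alone: its
      # background-corrected integrated intensity is exactly cl$intensity.
      img[d] <- background + cl$intensity / sum(d)
    }
    list(image = add_noise(img), cell_mask = cell_mask,
         cluster_mask = cluster_mask)
  }

  mid_y <- 5 + wid_px / 2
  mother <- make_frame(
    cell_spans = list(c(1L, len_px)),
    clusters = list(list(cy = mid_y, cx = 5 + len_px / 2,
                         intensity = cluster_intensity))
  )

  half <- len_px %/% 2L
  d1_span <- c(1L, half - 1L)            # 1-px septum gap
  d2_span <- c(half + 1L, len_px)
  if (mode == "fission") {
    daughters <- make_frame(
      cell_spans = list(d1_span, d2_span),
      clusters = list(
        list(cy = mid_y, cx = 5 + mean(d1_span),
             intensity = conservation * asymmetry * cluster_intensity),
        list(cy = mid_y, cx = 5 + mean(d2_span),
             intensity = conservation * (1 - asymmetry) * cluster_intensity)
      )
    )
  } else {
    # Disintegration: diffuse signal carries the conserved fraction of the
    # mother's total background-corrected intensity.
    mother_area <- sum(mother$cell_mask > 0L)
    mother_cl_area <- sum(mother$cluster_mask > 0L)
    mother_total <- diffuse_intensity * (mother_area - mother_cl_area) +
      cluster_intensity
    d_area <- wid_px * (diff(d1_span) + 1L) + wid_px * (diff(d2_span) + 1L)
    d_diffuse <- conservation * mother_total / d_area
    daughters <- local({
      cell_mask <- blank()
      cell_mask[rows, cell_cols(d1_span[1L], d1_span[2L])] <- 1L
      cell_mask[rows, cell_cols(d2_span[1L], d2_span[2L])] <- 2L
      img <- matrix(background, ny, nx)
      img[cell_mask > 0L] <- background + d_diffuse
      list(image = add_noise(img), cell_mask = cell_mask,
           cluster_mask = blank())
    })
  }

  truth <- structure(
    list(conservation = conservation, asymmetry = asymmetry, mode = mode,
         mother_cluster_intensity = cluster_intensity),
    class = "division_truth"
  )
  structure(list(frames = list(pre = mother, post = daughters), truth = truth),
            class = "division_event")
}
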