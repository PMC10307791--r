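#' Separation factor: percent of total fluorescence in the condensed phase
#'
#' The separation factor is the integrated intensity inside segmented
#' condensates over the total integrated intensity of the image, in percent.
#' No background subtraction is applied. Computed on the maximum intensity
#' projection by convention.
#'
#' @param image 2-d numeric matrix (typically a max projection).
#' @param condensates A `condensate_set` or a label matrix.
#' @return One-row tibble: `separation_factor` (percent), `integrated_in`,
#'   `integrated_total`, `n_objects`.
#' @export
#' @examples
#' img <- matrix(1, 4, 4); img[1:2, 1:2] <- 10
#' lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
#' separation_factor(img, lab)  # 100 * 40 / 52
separation_factor <- function(image, condensates) {
  lab <- as_label_map(condensates)
  stopifnot(all(dim(lab) == dim(image)))
  total <- sum(image)
  if (total <= 0) stop("all-zero image: separation factor undefined", call. = FALSE)
  inside <- sum(image[lab > 0L])
  tibble::tibble(
    separation_factor = 100 * inside / total,
    integrated_in = inside,
    integrated_total = total,
    n_objects = length(unique(lab[lab > 0L]))
  )
}

#' Client enrichment in condensates, with bleedthrough correction
#'
#' Enrichment is the mean client-channel intensity inside the condensates
#' (segmented on the scaffold channel, best-focus slice) over the mean
#' intensity in the remaining areas of the field of view. The corrected
#' enrichment subtracts the raw enrichment of a bleedthrough control (the
#' same imaging with no client added). The within-condensate CV
#' (SD/mean of client intensity over condensate pixels) quantifies how
#' heterogeneously the client distributes in the dense phase.
#'
#' @param client_image 2-d client-channel image (best-focus slice).
#' @param condensates A `condensate_set` or label matrix from the scaffold
#'   channel.
#' @param bleedthrough_raw_enrichment Raw enrichment of the no-client
#'   control; 0 for no correction.
#' @return One-row tibble: `raw_enrichment`, `corrected_enrichment`,
#'   `condensate_cv`, `mean_inside`, `mean_outside`.
#' @export
client_enrichment <- function(client_image, condensates,
                              bleedthrough_raw_enrichment = 0) {
  lab <- as_label_map(condensates)
  stopifnot(all(dim(lab) == dim(client_image)))
  inside <- client_image[lab > 0L]
  outside <- client_image[lab == 0L]
  if (length(inside) == 0L) stop("no condensate pixels", call. = FALSE)
  m_out <- mean(outside)
  if (!is.finite(m_out) || m_out <= 0) {
    stop("mean outside intensity is zero: enrichment undefined", call. = FALSE)
  }
  raw <- mean(inside) / m_out
  tibble::tibble(
    raw_enrichment = raw,
    corrected_enrichment = raw - bleedthrough_raw_enrichment,
    condensate_cv = sd_pop(inside) / mean(inside),
    mean_inside = mean(inside),
    mean_outside = m_out
  )
}

#' Expected enrichment inflation from differential degree of labeling
#'
#' When two clients carry different average numbers of dye molecules per
#' protein, per-molecule fluorescence alone would inflate the enrichment of
#' the more heavily labeled client by the ratio of the degrees of labeling.
#' Comparing this expected fold to the observed enrichment ratio tests
#' whether partitioning is specific rather than a labeling artifact.
#'
#' @param dol_a Degree of labeling (dyes/protein) of the reference client.
#' @param dol_b Degree of labeling of the comparison client.
#' @return The fold `dol_a / dol_b`.
#' @export
#' @examples
#' expected_labeling_ratio(19, 0.5)  # 38
expected_labeling_ratio <- function(dol_a, dol_b) {
  if (dol_a <= 0 || dol_b <= 0) {
    stop("degrees of labeling must be > 0", call. = FALSE)
  }
  dol_a / dol_b
}
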