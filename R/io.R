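# File I/O: multi-page TIFF with a JSON sidecar carrying axes, calibration
# and intensity scale (TIFF tags are dialect-prone; the sidecar is
# authoritative), plus the CSV dialects used across the package
# (UTF-8, comma separator, '.' decimal, header row).

#' Write an image scene as multi-page TIFF with JSON sidecar
#'
#' Pages are written z-major, channel-minor: for each z-slice, all channels
#' in order. Intensities are stored as 32-bit samples scaled to `[0, 1]`;
#' the scale factor, axis sizes, channel names and pixel size go into
#' `<path>.json`, which [read_scene_tiff()] uses to reconstruct the scene
#' exactly.
#'
#' @param scene An [image_scene()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "image_scene"))
  d <- dim(scene$data)
  scale <- max(scene$data, 1e-12)
  pages <- list()
  for (z in seq_len(d[4L])) {
    for (ch in seq_len(d[3L])) {
      pages[[length(pages) + 1L]] <- scene$data[, , ch, z] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    axes = "y,x,channel,z", ny = d[1L], nx = d[2L],
    n_channels = d[3L], n_z = d[4L],
    page_order = "z-major, channel-minor",
    channel_names = scene$channel_names,
    pixel_size_nm = scene$pixel_size,
    intensity_scale = scale
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image scene written by [write_scene_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return An [image_scene()].
#' @export
read_scene_tiff <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path)) stop("missing JSON sidecar: ", sc_path, call. = FALSE)
  meta <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(meta$ny, meta$nx, meta$n_channels, meta$n_z))
  i <- 0L
  for (z in seq_len(meta$n_z)) {
    for (ch in seq_len(meta$n_channels)) {
      i <- i + 1L
      arr[, , ch, z] <- pages[[i]] * meta$intensity_scale
    }
  }
  image_scene(arr, pixel_size = meta$pixel_size_nm,
              channel_names = meta$channel_names)
}

#' Read a FRAP trace CSV
#'
#' Expected columns: `time_min`, `roi`, `roi_bg`, `cell`, `cell_bg`,
#' `phase` ("pre"/"post"). `cell`/`cell_bg` may be absent for in vitro
#' traces.
#'
#' @param path CSV path.
#' @return Tibble in the format [normalize_frap_trace()] consumes.
#' @export
read_frap_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "roi", "roi_bg", "phase")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("FRAP CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Read a plate-reader absorbance CSV (long format)
#'
#' Expected columns: `well`, `time_min`, `a340`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_min", "a340")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("plate CSV missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Process a plate of absorbance traces into hydrolysis rates
#'
#' Joins a long-format plate CSV with a plate map (columns `well`,
#' `condition`, `enzyme_uM`, `control_well`), subtracts each well's control,
#' and extracts the hydrolysis rate per well.
#'
#' @param plate Tibble from [read_plate_csv()] (or equivalent).
#' @param plate_map Tibble with `well`, `condition`, `enzyme_uM`,
#'   `control_well`.
#' @param ... Passed to [hydrolysis_rate()].
#' @return Tibble, one row per non-control well, with condition metadata and
#'   the [hydrolysis_rate()] columns.
#' @export
gtpase_plate <- function(plate, plate_map, ...) {
  wells <- plate_map[!is.na(plate_map$control_well) &
                       plate_map$control_well != "", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    rx <- plate[plate$well == w$well, c("time_min", "a340")]
    ct <- plate[plate$well == w$control_well, c("time_min", "a340")]
    corrected <- subtract_control(rx, ct)
    dplyr::bind_cols(
      tibble::tibble(well = w$well, condition = w$condition,
                     enzyme_uM = w$enzyme_uM),
      hydrolysis_rate(corrected, enzyme_uM = w$enzyme_uM, ...)
    )
  })
}

# Fixed CSV dialect for outputs.
write_csv_out <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
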