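# Run configuration and stage execution. A saved config re-executed with
# run_stage() reproduces the outputs of deterministic stages bit-identically;
# every output directory receives a manifest (hashed inputs, parameters,
# package version, seed) sufficient to reproduce it.

stage_defaults <- list(
  simulate = list(
    what = "condensates",     # condensates|filaments|frap|division|cells|absorbance
    image_shape = c(128L, 128L),
    pixel_size = 207.6,
    psf_sigma = 100,
    poisson_scale = 50,
    read_sigma = 0.5,
    n_objects = 25
  ),
  quantify = list(
    input = NULL,              # scene TIFF
    mode = "separation",       # separation|enrichment|cv|network
    condensate_channel = 1L,
    client_channel = 2L,
    smooth_sigma = 1,
    k_seg = 3,
    min_area_px = 9L,
    k = 3,
    bleedthrough = 0,
    reference_cv = NULL,
    reference_mean = NULL,
    watershed = FALSE
  ),
  frap = list(
    input = NULL,              # one or more trace CSVs
    mode = "in_vivo"
  ),
  cellcycle = list(
    input = NULL,              # cells CSV: cell_id, cell_length_um, long_axis_um, n_clusters
    axis = "long_axis_um"
  ),
  gtpase = list(
    plate = NULL,
    plate_map = NULL,
    epsilon = 6220,
    path_cm = 0.248,
    window_min = 20
  ),
  report = list(
    input = NULL               # directory of stage outputs
  )
)

#' Load and validate a run configuration
#'
#' Reads a JSON run config (`stage`, `seed`, `out`, `params`), fills stage
#' defaults (e.g. `min_area_px = 9`, `k = 3` for quantification), and rejects
#' unknown keys with field-level messages.
#'
#' @param path JSON config path.
#' @return List of class `run_config`: `stage`, `seed`, `out`, `params`
#'   (defaults filled), `version`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(raw)
}

#' @rdname load_run_config
#' @param raw A list with the same structure as the JSON file (for building
#'   configs programmatically).
#' @export
validate_run_config <- function(raw) {
  allowed_top <- c("stage", "seed", "out", "params")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$stage) || !raw$stage %in% names(stage_defaults)) {
    stop("`stage` must be one of: ", paste(names(stage_defaults), collapse = ", "),
         call. = FALSE)
  }
  defaults <- stage_defaults[[raw$stage]]
  params <- raw$params %||% list()
  unknown_p <- setdiff(names(params), names(defaults))
  if (length(unknown_p) > 0L) {
    stop("unknown parameter(s) for stage '", raw$stage, "': ",
         paste(unknown_p, collapse = ", "), call. = FALSE)
  }
  filled <- utils::modifyList(defaults, params, keep.null = TRUE)
  structure(list(
    stage = raw$stage,
    seed = as.integer(raw$seed %||% 1L),
    out = raw$out %||% ".",
    params = filled,
    version = as.character(utils::packageVersion("condenser"))
  ), class = "run_config")
}

#' Save a run configuration as JSON
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(
    list(stage = config$stage, seed = config$seed, out = config$out,
         params = config$params),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Execute a pipeline stage from a run configuration
#'
#' Dispatches on `config$stage`, writes the stage's CSV/TIFF outputs under
#' `config$out`, and drops a `manifest.json` beside them recording the
#' parameters, seed, package version and MD5 hashes of all inputs. Stage
#' failures propagate as errors naming the failing operation; no outputs are
#' written when inputs are missing.
#'
#' @param config A `run_config` from [load_run_config()] /
#'   [validate_run_config()].
#' @return Invisibly, a list with `outputs` (paths written) and `manifest`.
#' @export
run_stage <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  inputs <- character()
  for (key in c("input", "plate", "plate_map")) {
    if (!is.null(p[[key]])) inputs <- c(inputs, unlist(p[[key]]))
  }
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0L) {
    stop("missing input path(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  outputs <- switch(
    config$stage,
    simulate = stage_simulate(config),
    quantify = stage_quantify(config),
    frap = stage_frap(config),
    cellcycle = stage_cellcycle(config),
    gtpase = stage_gtpase(config),
    report = stage_report(config)
  )
  manifest <- list(
    stage = config$stage, seed = config$seed,
    params = config$params, version = config$version,
    inputs = if (length(inputs) > 0L) {
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    } else list(),
    outputs = outputs
  )
  manifest_path <- file.path(config$out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  message(sprintf("[%s] wrote %d output(s) to %s", config$stage,
                  length(outputs), config$out))
  invisible(list(outputs = outputs, manifest = manifest))
}

stage_simulate <- function(config) {
  p <- config$params
  cfg <- scene_config(image_shape = p$image_shape, pixel_size = p$pixel_size,
                      psf_sigma = p$psf_sigma, poisson_scale = p$poisson_scale,
                      read_sigma = p$read_sigma, seed = config$seed)
  if (!p$what %in% c("condensates", "filaments")) {
    stop("run_stage(simulate) writes image scenes; use the simulate_* functions for traces",
         call. = FALSE)
  }
  sim <- if (p$what == "condensates") {
    simulate_condensate_scene(cfg, n_objects = p$n_objects)
  } else {
    simulate_filament_scene(cfg)
  }
  scene_path <- file.path(config$out, paste0(p$what, ".tiff"))
  write_scene_tiff(sim$scene, scene_path)
  truth_path <- file.path(config$out, "truth.json")
  truth <- sim$truth
  truth$centers <- NULL  # tables go to CSV, scalars to JSON
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE, digits = NA)
  out <- c(scene_path, paste0(scene_path, ".json"), truth_path)
  if (!is.null(sim$truth$centers)) {
    centers_path <- file.path(config$out, "truth_objects.csv")
    write_csv_out(sim$truth$centers, centers_path)
    out <- c(out, centers_path)
  }
  out
}

stage_quantify <- function(config) {
  p <- config$params
  scene <- read_scene_tiff(p$input)
  mip <- max_intensity_projection(scene, p$condensate_channel)
  lab <- segment_condensates(mip, smooth_sigma = p$smooth_sigma,
                             k_seg = p$k_seg, watershed = p$watershed)
  cset <- screen_condensates(lab, mip, min_area_px = p$min_area_px, k = p$k,
                             pixel_size = scene$pixel_size)
  res <- switch(
    p$mode,
    separation = separation_factor(mip, cset),
    enrichment = {
      z <- best_focus_slice(scene, p$condensate_channel)
      sl <- get_plane(scene, p$condensate_channel, z)
      lab_sl <- segment_condensates(sl, smooth_sigma = p$smooth_sigma,
                                    k_seg = p$k_seg, watershed = p$watershed)
      cset_sl <- screen_condensates(lab_sl, sl, min_area_px = p$min_area_px,
                                    k = p$k)
      client_enrichment(get_plane(scene, p$client_channel, z), cset_sl,
                        bleedthrough_raw_enrichment = p$bleedthrough)
    },
    cv = image_cv(mip, reference_cv = p$reference_cv),
    network = network_intensity(scene, p$condensate_channel,
                                reference_mean = p$reference_mean),
    stop("unknown quantify mode: ", p$mode, call. = FALSE)
  )
  res_path <- file.path(config$out, paste0("quantify_", p$mode, ".csv"))
  write_csv_out(res, res_path)
  obj_path <- file.path(config$out, "objects.csv")
  write_csv_out(cset$objects, obj_path)
  message(sprintf("[quantify] %d objects segmented, %d retained after screening",
                  length(unique(lab[lab > 0])), nrow(cset$objects)))
  c(res_path, obj_path)
}

stage_frap <- function(config) {
  p <- config$params
  paths <- unlist(p$input)
  traces <- lapply(paths, function(f) {
    normalize_frap_trace(read_frap_csv(f), mode = p$mode)
  })
  fits <- dplyr::bind_rows(lapply(seq_along(traces), function(i) {
    dplyr::mutate(glance(fit_frap_recovery(traces[[i]])),
                  file = basename(paths[i]), .before = 1)
  }))
  fits_path <- file.path(config$out, "frap_fits.csv")
  write_csv_out(fits, fits_path)
  out <- fits_path
  if (length(traces) >= 2L) {
    agg <- aggregate_frap(traces)
    curve_path <- file.path(config$out, "frap_mean_curve.csv")
    write_csv_out(agg$curve, curve_path)
    out <- c(out, curve_path)
  }
  out
}

stage_cellcycle <- function(config) {
  p <- config$params
  cells <- tibble::as_tibble(utils::read.csv(p$input, stringsAsFactors = FALSE))
  reg <- axis_length_regression(cells, axis = p$axis)
  counts <- count_clusters(cells)
  reg_path <- file.path(config$out, "axis_scaling.csv")
  write_csv_out(reg, reg_path)
  counts_path <- file.path(config$out, "cluster_counts.csv")
  write_csv_out(counts$histogram, counts_path)
  c(reg_path, counts_path)
}

stage_gtpase <- function(config) {
  p <- config$params
  plate <- read_plate_csv(p$plate)
  plate_map <- tibble::as_tibble(utils::read.csv(p$plate_map,
                                                 stringsAsFactors = FALSE))
  res <- gtpase_plate(plate, plate_map, window_min = p$window_min,
                      epsilon = p$epsilon, path_cm = p$path_cm)
  res_path <- file.path(config$out, "gtpase_rates.csv")
  write_csv_out(res, res_path)
  res_path
}

stage_report <- function(config) {
  p <- config$params
  csvs <- list.files(p$input, pattern = "\\.csv$", full.names = TRUE,
                     recursive = TRUE)
  summary <- purrr::map_dfr(csvs, function(f) {
    d <- utils::read.csv(f)
    tibble::tibble(file = f, n_rows = nrow(d), n_cols = ncol(d))
  })
  report_path <- file.path(config$out, "report.csv")
  write_csv_out(summary, report_path)
  report_path
}
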