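#' Simulate a raw FRAP time series with acquisition photobleaching
#'
#' Generates the four raw signals a FRAP experiment records — bleached-ROI
#' intensity, its background, whole-cell intensity and its background — from
#' an underlying single-exponential recovery
#' \deqn{r(t) = plateau + (bleach\_depth - plateau) \, e^{-t/\tau}}
#' (relative to the pre-bleach level of 1). Acquisition photobleaching is a
#' multiplicative decay `exp(-photobleach_rate * t)` applied to ROI and
#' whole-cell signals alike, so double normalization cancels it exactly.
#' Ground truth (`tau`, `t_half = tau * log(2)`) is exported.
#'
#' @param tau Recovery time constant in minutes (> 0).
#' @param bleach_depth Fraction of the pre-bleach signal remaining at t = 0+.
#' @param plateau Recovery plateau as a fraction of pre-bleach signal;
#'   `0 <= bleach_depth <= plateau <= 1`.
#' @param photobleach_rate Acquisition photobleaching rate (per min).
#' @param background_level Constant background offset (intensity units).
#' @param timepoints Post-bleach acquisition times in minutes, strictly
#'   increasing, starting at the first post-bleach frame (t = 0 allowed).
#' @param n_prebleach Number of pre-bleach frames (>= 2), spaced like the
#'   first post-bleach interval, at negative times.
#' @param noise_sigma Gaussian noise SD added to every raw signal.
#' @param cell_intensity Whole-cell intensity before decay.
#' @param roi_fraction Fraction of cell signal in the ROI before bleaching.
#' @param seed Integer seed.
#'
#' @return List with `trace` (tibble: `time_min`, `phase` ("pre"/"post"),
#'   `roi`, `roi_bg`, `cell`, `cell_bg`) and `truth` (list of class
#'   `frap_series_truth` incl. `t_half`).
#' @export
#' @examples
#' sim <- simulate_frap_series(tau = 3, noise_sigma = 0)
#' sim$truth$t_half
simulate_frap_series <- function(tau,
                                 bleach_depth = 0.3,
                                 plateau = 0.9,
                                 photobleach_rate = 0,
                                 background_level = 0,
                                 timepoints = seq(0, 20, by = 0.5),
                                 n_prebleach = 5,
                                 noise_sigma = 0,
                                 cell_intensity = 1000,
                                 roi_fraction = 0.1,
                                 seed = 1L) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (!(bleach_depth >= 0 && bleach_depth <= plateau && plateau <= 1)) {
    stop("need 0 <= bleach_depth <= plateau <= 1", call. = FALSE)
  }
  if (n_prebleach < 2L) stop("need >= 2 pre-bleach frames", call. = FALSE)
  if (any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  }
  dt <- if (length(timepoints) > 1L) diff(timepoints)[1L] else 1
  t_pre <- -rev(seq_len(n_prebleach)) * dt
  tt <- c(t_pre, timepoints)
  phase <- rep(c("pre", "post"), c(n_prebleach, length(timepoints)))

  r <- ifelse(phase == "pre", 1,
              plateau + (bleach_depth - plateau) * exp(-tt / tau))
  decay <- exp(-photobleach_rate * (tt - tt[1L]))
  cell_sig <- cell_intensity * decay
  roi_sig <- roi_fraction * r * cell_sig

  set.seed(as.integer(seed))
  noisy <- function(x) x + if (noise_sigma > 0) {
    stats::rnorm(length(x), 0, noise_sigma)
  } else 0
  trace <- tibble::tibble(
    time_min = tt,
    phase = phase,
    roi = noisy(roi_sig + background_level),
    roi_bg = noisy(rep(background_level, length(tt))),
    cell = noisy(cell_sig + background_level),
    cell_bg = noisy(rep(background_level, length(tt)))
  )
  truth <- structure(list(
    tau = tau, t_half = tau * log(2), bleach_depth = bleach_depth,
    plateau = plateau, photobleach_rate = photobleach_rate,
    background_level = background_level
  ), class = "frap_series_truth")
  list(trace = trace, truth = truth)
}
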