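#' Normalize a raw FRAP trace
#'
#' Two conventions are supported. `"in_vivo"` is the double normalization:
#' after background correction, ROI intensity is divided by whole-cell
#' intensity, which cancels any multiplicative acquisition photobleaching
#' shared by both signals; the result is scaled so the mean of the pre-bleach
#' frames is exactly 100. `"in_vitro"` scales the background-corrected ROI
#' intensity alone so the pre-bleach mean is 100.
#'
#' @param trace Tibble with columns `time_min`, `phase` ("pre"/"post"),
#'   `roi`, `roi_bg`, and (for in vivo) `cell`, `cell_bg` — the format
#'   produced by [simulate_frap_series()] and [read_frap_csv()].
#' @param mode `"in_vivo"` or `"in_vitro"`.
#' @return Tibble: `time_min`, `phase`, `normalized` (percent of pre-bleach).
#' @export
normalize_frap_trace <- function(trace, mode = c("in_vivo", "in_vitro")) {
  mode <- match.arg(mode)
  need <- c("time_min", "phase", "roi", "roi_bg")
  if (mode == "in_vivo") need <- c(need, "cell", "cell_bg")
  missing_cols <- setdiff(need, names(trace))
  if (length(missing_cols) > 0L) {
    stop("trace is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(trace$time_min) <= 0)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  if (!any(trace$phase == "pre")) stop("no pre-bleach frames", call. = FALSE)
  roi_corr <- trace$roi - trace$roi_bg
  if (mode == "in_vivo") {
    denom <- trace$cell - trace$cell_bg
    bad <- which(denom <= 0)
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-positive corrected whole-cell intensity at frame %d (t = %g min)",
        bad[1L], trace$time_min[bad[1L]]), call. = FALSE)
    }
    rel <- roi_corr / denom
  } else {
    rel <- roi_corr
  }
  anchor <- mean(rel[trace$phase == "pre"])
  if (anchor <= 0) stop("non-positive pre-bleach mean", call. = FALSE)
  tibble::tibble(time_min = trace$time_min, phase = trace$phase,
                 normalized = 100 * rel / anchor)
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of `y = y0 + A * exp(-x / t)` to the post-bleach points
#' of a normalized trace (y in percent of pre-bleach, x in minutes from the
#' first post-bleach frame). `A` is negative for a recovery; the half-maximal
#' recovery time is `t_half = t * log(2)`. Initialization is deterministic:
#' `y0` from the tail of the series, `A` from the first post-bleach point,
#' `t` from the first crossing of `y0 + A/e` (falling back to half the time
#' span), with `t` bounded in `(0, 100 x span]`. A flat series (amplitude
#' indistinguishable from zero) or optimizer failure returns
#' `converged = FALSE` with diagnostics rather than an error.
#'
#' @param normalized Tibble from [normalize_frap_trace()], or a numeric
#'   vector of normalized values (then `time` must be given).
#' @param time Optional numeric time vector (minutes) when `normalized` is a
#'   bare vector.
#' @return An object of class `frap_fit`; see [tidy.frap_fit()] /
#'   [glance.frap_fit()]. Fields: `y0`, `A`, `t`, `t_half`, `rss`,
#'   `converged`, `n_points`, `data` (the fitted points), `note`.
#' @export
fit_frap_recovery <- function(normalized, time = NULL) {
  if (is.data.frame(normalized)) {
    post <- normalized[normalized$phase == "post", , drop = FALSE]
    x <- post$time_min
    y <- post$normalized
  } else {
    if (is.null(time)) stop("supply `time` with a bare numeric series", call. = FALSE)
    x <- time
    y <- as.numeric(normalized)
  }
  if (length(y) < 5L) stop("need >= 5 post-bleach points", call. = FALSE)
  x <- x - x[1L]
  span <- max(x) - min(x)

  n_tail <- max(1L, ceiling(0.1 * length(y)))
  y0_init <- mean(utils::tail(y, n_tail))
  a_init <- y[1L] - y0_init
  target <- y0_init + a_init / exp(1)
  cross <- if (a_init < 0) which(y >= target) else which(y <= target)
  t_init <- if (length(cross) > 0L && x[cross[1L]] > 0) x[cross[1L]] else span / 2
  t_init <- min(max(t_init, span * 1e-3), 100 * span)

  make_fit <- function(converged, y0, A, t, rss, note = NA_character_) {
    structure(list(
      y0 = y0, A = A, t = t,
      t_half = if (converged) t * log(2) else NA_real_,
      rss = rss, converged = converged, n_points = length(y),
      immobile_fraction = if (converged) (100 - (y0)) / (100 - (y0 + A)) else NA_real_,
      data = tibble::tibble(time_min = x, normalized = y),
      note = note
    ), class = "frap_fit")
  }

  # Amplitude indistinguishable from zero makes t unidentifiable.
  if (abs(a_init) < 1e-8 * max(abs(y), 1) ||
      sd_pop(y) < 1e-10 * max(abs(y), 1)) {
    return(make_fit(FALSE, y0 = mean(y), A = 0, t = NA_real_,
                    rss = sum((y - mean(y))^2),
                    note = "flat series: recovery amplitude ~ 0, t unidentifiable"))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + A * exp(-x / t),
      start = list(y0 = y0_init, A = a_init, t = t_init),
      lower = c(-Inf, -Inf, span * 1e-6),
      upper = c(Inf, Inf, 100 * span),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(make_fit(FALSE, y0 = y0_init, A = a_init, t = NA_real_,
                    rss = NA_real_, note = conditionMessage(fit)))
  }
  cf <- stats::coef(fit)
  make_fit(TRUE, y0 = unname(cf["y0"]), A = unname(cf["A"]),
           t = unname(cf["t"]), rss = sum(stats::resid(fit)^2))
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<frap_fit> y = %.2f + %.2f * exp(-x/%.3f);  t_half = %.3f min (n = %d, rss = %.3g)\n",
      x$y0, x$A, x$t, x$t_half, x$n_points, x$rss))
  } else {
    cat(sprintf("<frap_fit> not converged: %s\n", x$note))
  }
  invisible(x)
}

#' Tidy a FRAP fit into one row per parameter
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    term = c("y0", "A", "t", "t_half"),
    estimate = c(x$y0, x$A, x$t, x$t_half)
  )
}

#' One-row summary of a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return One-row tibble: `y0`, `A`, `t`, `t_half`, `rss`, `converged`,
#'   `n_points`.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(y0 = x$y0, A = x$A, t = x$t, t_half = x$t_half,
                 rss = x$rss, converged = x$converged, n_points = x$n_points)
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics in the broom style, so fitted objects
#' from this package summarise into tibbles.
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Aggregate multiple FRAP bleaching events
#'
#' Resamples each normalized trace onto a common post-bleach time grid by
#' linear interpolation, reports the per-timepoint mean and SD curve, fits
#' the mean curve with [fit_frap_recovery()], and collects per-event fit
#' summaries.
#'
#' @param traces List of normalized traces (tibbles from
#'   [normalize_frap_trace()]); at least 2.
#' @param grid_points Number of points in the common grid.
#' @return List of class `frap_aggregate`: `curve` (tibble `time_min`,
#'   `mean`, `stdev`, `n`), `pooled_fit` (`frap_fit` of the mean curve),
#'   `event_fits` (tibble, one row per event via [glance.frap_fit()]).
#' @export
aggregate_frap <- function(traces, grid_points = 50L) {
  if (length(traces) < 2L) stop("need >= 2 bleaching events", call. = FALSE)
  posts <- lapply(traces, function(tr) tr[tr$phase == "post", , drop = FALSE])
  lo <- max(vapply(posts, function(p) min(p$time_min), numeric(1)))
  hi <- min(vapply(posts, function(p) max(p$time_min), numeric(1)))
  if (hi <= lo) stop("traces have disjoint post-bleach time ranges", call. = FALSE)
  grid <- seq(lo, hi, length.out = grid_points)
  mat <- vapply(posts, function(p) {
    stats::approx(p$time_min, p$normalized, xout = grid)$y
  }, numeric(grid_points))
  curve <- tibble::tibble(
    time_min = grid,
    mean = rowMeans(mat),
    stdev = apply(mat, 1, sd_pop),
    n = ncol(mat)
  )
  pooled <- fit_frap_recovery(curve$mean, time = curve$time_min)
  event_fits <- dplyr::bind_rows(
    lapply(seq_along(traces), function(i) {
      dplyr::mutate(glance(fit_frap_recovery(traces[[i]])), event = i,
                    .before = 1)
    })
  )
  structure(list(curve = curve, pooled_fit = pooled, event_fits = event_fits),
            class = "frap_aggregate")
}

#' @export
print.frap_aggregate <- function(x, ...) {
  cat(sprintf("<frap_aggregate> %d events on a %d-point grid\n",
              x$curve$n[1L], nrow(x$curve)))
  print(x$pooled_fit)
  invisible(x)
}
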