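## Hypotension exposure metrics.
##
## The exposure of interest is the area between a threshold line T (default
## 65 mmHg) and the piecewise-linear MAP curve, counted only where
## MAP < T, integrated by the composite trapezoidal rule over an analysis
## window; dividing by the window duration gives the time-weighted average
## (TWA) depth of hypotension in mmHg.

# Clip a sampled series to [t_start, t_stop], interpolating MAP at the
# window boundaries when samples straddle them. Returns t (seconds) and v.
clip_series_to_window <- function(t, v, t_start, t_stop) {
  if (length(t) < 2L) stop("insufficient_samples", call. = FALSE)
  if (t[1L] >= t_stop || t[length(t)] <= t_start)
    stop("window outside sampled range", call. = FALSE)
  lo <- max(t_start, t[1L])
  hi <- min(t_stop, t[length(t)])
  inside <- t > lo & t < hi
  ti <- c(lo, t[inside], hi)
  vi <- stats::approx(t, v, xout = ti, rule = 1)$y
  list(t = ti, v = vi)
}

# Insert the exact threshold-crossing points of the piecewise-linear curve.
insert_threshold_crossings <- function(t, v, threshold) {
  d1 <- v[-length(v)] - threshold
  d2 <- v[-1L] - threshold
  cross <- which(d1 * d2 < 0)
  if (!length(cross)) return(list(t = t, v = v))
  tc <- t[cross] + (threshold - v[cross]) * (t[cross + 1L] - t[cross]) /
    (v[cross + 1L] - v[cross])
  ord <- order(c(t, tc))
  list(t = c(t, tc)[ord], v = c(v, rep(threshold, length(tc)))[ord])
}

#' Area under the threshold (deficit AUC) for a MAP series
#'
#' Computes the area between the threshold line and the piecewise-linear
#' MAP curve over an analysis window, counting only the region where
#' MAP is below the threshold, using the composite trapezoidal rule.
#' Samples just outside the window are used only to interpolate MAP onto
#' the window boundaries.
#'
#' With `interpolate_crossings = TRUE` (default) the exact points where
#' the linear MAP segments cross the threshold are inserted first, which
#' makes the trapezoidal sum exact for the piecewise-linear curve. With
#' `FALSE` the trapezoid is applied to the clipped deficits
#' `max(0, T - MAP)` at the sample points only — a documented alternative
#' reading of "AUC between the threshold and the MAP measurements".
#'
#' @param series a [map_series].
#' @param window an [analysis_window].
#' @param threshold threshold T in mmHg (default 65).
#' @param interpolate_crossings insert threshold crossings before
#'   integrating (default `TRUE`).
#' @return deficit AUC in mmHg·min (non-negative scalar).
#' @export
deficit_auc <- function(series, window, threshold = 65,
                        interpolate_crossings = TRUE) {
  stopifnot(inherits(series, "map_series"), inherits(window, "analysis_window"),
            threshold > 0)
  cl <- clip_series_to_window(series$t, series$value, window$t_start, window$t_stop)
  if (length(cl$t) < 2L) stop("insufficient_samples", call. = FALSE)
  if (interpolate_crossings) cl <- insert_threshold_crossings(cl$t, cl$v, threshold)
  tm <- cl$t / 60                      # minutes
  d  <- pmax(0, threshold - cl$v)      # deficit, mmHg
  sum(diff(tm) * (d[-length(d)] + d[-1L]) / 2)
}

#' Time-weighted average MAP below threshold and exposure summary
#'
#' `twa_below()` divides the deficit AUC by the full window duration
#' ("AUC divided by total CPB time") and returns an exposure summary with
#' supporting quality metrics.
#'
#' @inheritParams deficit_auc
#' @return a list of class `exposure_summary` with fields `threshold`
#'   (mmHg), `auc_below` (mmHg·min), `twa_below` (mmHg), `minutes_below`
#'   (min of interpolated MAP < T), `window_duration` (min), `n_samples`
#'   (samples inside the window), and `max_gap` (largest inter-sample gap
#'   within the window including the edges, min).
#' @export
twa_below <- function(series, window, threshold = 65,
                      interpolate_crossings = TRUE) {
  auc <- deficit_auc(series, window, threshold, interpolate_crossings)
  dur_min <- (window$t_stop - window$t_start) / 60
  cl <- clip_series_to_window(series$t, series$value, window$t_start, window$t_stop)
  cr <- insert_threshold_crossings(cl$t, cl$v, threshold)
  dmid <- (pmax(0, threshold - cr$v[-length(cr$v)]) +
           pmax(0, threshold - cr$v[-1L])) / 2
  minutes_below <- sum(diff(cr$t / 60)[dmid > 0])
  inside <- series$t >= window$t_start & series$t <= window$t_stop
  structure(list(
    threshold       = threshold,
    auc_below       = auc,
    twa_below       = auc / dur_min,
    minutes_below   = minutes_below,
    window_duration = dur_min,
    n_samples       = sum(inside),
    max_gap         = window_max_gap(series$t[inside], window)
  ), class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf(paste0("<exposure_summary> T=%g mmHg: AUC %.2f mmHg*min, ",
                     "TWA %.3f mmHg, %.1f/%.1f min below, %d samples, max gap %.2f min\n"),
              x$threshold, x$auc_below, x$twa_below, x$minutes_below,
              x$window_duration, x$n_samples, x$max_gap))
  invisible(x)
}

window_max_gap <- function(t_inside, window) {
  gaps <- diff(c(window$t_start, t_inside, window$t_stop)) / 60
  if (!length(gaps)) (window$t_stop - window$t_start) / 60 else max(gaps)
}

#' Check sampling resolution inside a window
#'
#' Eligibility requires MAP at (at least) five-minute resolution. The check
#' passes iff every inter-sample gap within the window — including the gaps
#' from `t_start` to the first inside sample and from the last inside
#' sample to `t_stop` — is at most `max_allowed_gap` minutes (boundary
#' inclusive).
#'
#' @param series a [map_series].
#' @param window an [analysis_window].
#' @param max_allowed_gap maximum allowed gap in minutes (default 5).
#' @return list with `ok` (logical), `max_gap` (minutes), and `reason`
#'   (`NA` when ok).
#' @export
resolution_check <- function(series, window, max_allowed_gap = 5) {
  stopifnot(inherits(series, "map_series"), inherits(window, "analysis_window"))
  inside <- series$t >= window$t_start & series$t <= window$t_stop
  if (!any(inside)) {
    return(list(ok = FALSE, max_gap = (window$t_stop - window$t_start) / 60,
                reason = "no_samples_in_window"))
  }
  mg <- window_max_gap(series$t[inside], window)
  ok <- mg <= max_allowed_gap + 1e-9
  list(ok = ok, max_gap = mg, reason = if (ok) NA_character_ else "insufficient_resolution")
}
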