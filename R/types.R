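#' Construct a MAP series for one operation
#'
#' A `map_series` holds irregularly sampled invasive mean arterial pressure
#' (MAP) for a single operation. Times are seconds from surgery start;
#' values are mmHg. Samples are sorted and duplicate timestamps are
#' collapsed by averaging (an order-independent, unbiased policy).
#'
#' @param op_id opaque operation identifier (scalar).
#' @param t numeric vector of sample times, seconds from surgery start.
#' @param value numeric vector of MAP values, mmHg.
#' @param dedup collapse duplicate timestamps by averaging (default `TRUE`).
#' @return an object of class `map_series` with fields `op_id`, `t`,
#'   `value`, and `n_dedup` (number of samples removed by deduplication).
#' @export
map_series <- function(op_id, t, value, dedup = TRUE) {
  stopifnot(length(t) == length(value))
  t <- as.numeric(t); value <- as.numeric(value)
  keep <- is.finite(t) & is.finite(value)
  t <- t[keep]; value <- value[keep]
  ord <- order(t)
  t <- t[ord]; value <- value[ord]
  n_dedup <- 0L
  if (dedup && anyDuplicated(t)) {
    n_in <- length(t)
    value <- as.numeric(tapply(value, t, mean))
    t <- sort(unique(t))
    n_dedup <- n_in - length(t)
  }
  structure(list(op_id = op_id, t = t, value = value, n_dedup = n_dedup),
            class = "map_series")
}

#' @export
print.map_series <- function(x, ...) {
  cat(sprintf("<map_series> op %s: %d samples, t in [%.0f, %.0f] s, MAP in [%.1f, %.1f] mmHg\n",
              as.character(x$op_id), length(x$t),
              if (length(x$t)) min(x$t) else NA, if (length(x$t)) max(x$t) else NA,
              if (length(x$t)) min(x$value) else NA, if (length(x$t)) max(x$value) else NA))
  invisible(x)
}

#' @export
length.map_series <- function(x) length(x$t)

#' Define an analysis window
#'
#' Windows delimit the period over which exposure is integrated:
#' typically the cardiopulmonary bypass (CPB) run (`"cpb"`) or the
#' post-bypass remainder of surgery (`"post_cpb"`).
#'
#' @param label window label, e.g. `"cpb"` or `"post_cpb"`.
#' @param t_start,t_stop window bounds in seconds from surgery start;
#'   `t_start < t_stop` is required.
#' @return an object of class `analysis_window`.
#' @export
analysis_window <- function(label, t_start, t_stop) {
  t_start <- as.numeric(t_start); t_stop <- as.numeric(t_stop)
  if (!is.finite(t_start) || !is.finite(t_stop) || t_start >= t_stop)
    stop("analysis_window requires finite t_start < t_stop", call. = FALSE)
  structure(list(label = label, t_start = t_start, t_stop = t_stop),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %s: [%.0f, %.0f] s (%.1f min)\n",
              x$label, x$t_start, x$t_stop, (x$t_stop - x$t_start) / 60))
  invisible(x)
}
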