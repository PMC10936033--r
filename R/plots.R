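## Base-graphics figures: the exposure trace with the shaded area under
## the threshold, and the predicted-probability curve with its band.

#' Plot a MAP trace with the area under the threshold shaded
#'
#' Draws the MAP series, the threshold as a horizontal dashed line, the
#' analysis-window bounds as vertical dashed lines, and shades the deficit
#' region (MAP below threshold inside the window).
#'
#' @param series a [map_series].
#' @param window optional [analysis_window] (CPB window).
#' @param threshold threshold in mmHg (default 65).
#' @return invisibly, `NULL`.
#' @export
plot_map_trace <- function(series, window = NULL, threshold = 65) {
  tm <- series$t / 60
  graphics::plot(tm, series$value, type = "l", lwd = 1.2,
                 xlab = "surgery time (min)", ylab = "MAP (mmHg)",
                 main = sprintf("MAP and area under %g mmHg", threshold))
  graphics::abline(h = threshold, col = "red", lty = 2)
  if (!is.null(window)) {
    graphics::abline(v = c(window$t_start, window$t_stop) / 60, lty = 2)
    cl <- clip_series_to_window(series$t, series$value,
                                window$t_start, window$t_stop)
    cr <- insert_threshold_crossings(cl$t, cl$v, threshold)
    yb <- pmin(cr$v, threshold)
    graphics::polygon(c(cr$t / 60, rev(cr$t / 60)),
                      c(yb, rep(threshold, length(yb))),
                      col = grDevices::adjustcolor("red", 0.3), border = NA)
  }
  invisible(NULL)
}

#' Plot a predicted-probability curve with its 95% band
#'
#' @param curve data.frame from [predicted_probability_curve()].
#' @param xlab,ylab axis labels.
#' @return invisibly, `NULL`.
#' @export
plot_probability_curve <- function(curve,
                                   xlab = "TWA-MAP under 65 mmHg (mmHg)",
                                   ylab = "predicted probability of CSA-AKI") {
  graphics::plot(curve$exposure, curve$p_hat, type = "n",
                 ylim = range(c(curve$lo, curve$hi)), xlab = xlab, ylab = ylab)
  graphics::polygon(c(curve$exposure, rev(curve$exposure)),
                    c(curve$lo, rev(curve$hi)),
                    col = grDevices::adjustcolor("red", 0.3), border = NA)
  graphics::lines(curve$exposure, curve$p_hat, lwd = 2)
  invisible(NULL)
}
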