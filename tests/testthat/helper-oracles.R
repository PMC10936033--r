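# Independent oracles and fixture builders used across the suite.

# Dense midpoint Riemann sum for the deficit AUC (mmHg*min), independent of
# the trapezoid-with-crossings implementation path. Cells are at most
# dt_min wide and aligned to the sample breakpoints, so the only
# discretization error left is at threshold crossings inside a cell.
riemann_deficit_auc <- function(t, v, t_start, t_stop, threshold, dt_min = 0.01) {
  knots <- sort(unique(c(t_start, t_stop, t[t > t_start & t < t_stop])))
  total <- 0
  for (k in seq_len(length(knots) - 1L)) {
    a <- knots[k]; b <- knots[k + 1L]
    m <- max(1L, ceiling((b - a) / (dt_min * 60)))
    mids <- a + (seq_len(m) - 0.5) * (b - a) / m
    mv <- stats::approx(t, v, xout = mids)$y
    total <- total + sum(pmax(0, threshold - mv)) * (b - a) / m / 60
  }
  total
}

# Random piecewise-linear MAP series spanning a window with margins.
# Sample spacing is at least 30 s (invasive-line charting resolution), so
# the 0.01-min oracle grid always resolves every linear segment.
random_map_case <- function() {
  dur <- runif(1, 10, 60) * 60                 # window 10-60 min, seconds
  gaps <- runif(ceiling(dur / 45) + 10, 45, 150)
  t <- cumsum(gaps)
  t <- c(0, t[t < dur + 200], dur + 240)       # guarantee window coverage
  # slow random walk around the threshold: physiologic slew rates, frequent
  # threshold crossings
  v <- pmin(pmax(68 + cumsum(rnorm(length(t), 0, 4)), 45), 95)
  list(series = map_series("case", t, v),
       window = analysis_window("cpb", 120, 120 + dur))
}

# Case-by-case KDIGO criterion table for a single postoperative peak.
# Comparisons use the same >=-with-1e-12-guard convention as the package
# (a floating-point tie-breaking convention, not the algorithm itself).
ge <- function(a, b) a >= b - 1e-12
kdigo_oracle_single_peak <- function(baseline, peak, peak_day, rrt = FALSE,
                                     horizon_days = 7) {
  stage <- 0L
  if (peak_day <= horizon_days) {
    rel <- ge(peak, 1.5 * baseline)
    abs48 <- ge(peak - baseline, 0.3) && peak_day <= 2
    if (rel || abs48) {
      stage <- 1L
      if (ge(peak / baseline, 2)) stage <- 2L
      if (ge(peak / baseline, 3)) stage <- 3L
      if (ge(peak, 4)) stage <- 3L
    }
  }
  if (rrt) stage <- 3L
  stage
}

# Write a minimal vitals/ops/labs/patients fixture as CSVs in a tempdir.
write_tiny_tables <- function(vitals, operations = NULL, labs = NULL,
                              patients = NULL, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list()
  ingest <- function(x, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(x, p)
    p
  }
  if (!is.null(vitals)) paths$vitals <- ingest(vitals, "vitals")
  if (!is.null(operations)) paths$operations <- ingest(operations, "operations")
  if (!is.null(labs)) paths$labs <- ingest(labs, "labs")
  if (!is.null(patients)) paths$patients <- ingest(patients, "patients")
  paths
}

# Analysis-ready cohort from a 2x2 table (exposed/unexposed x event/no-event).
cohort_2x2 <- function(a, b, c, d) {
  data.table::data.table(
    exposure = c(rep(1, a + b), rep(0, c + d)),
    aki = c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d)))
}
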