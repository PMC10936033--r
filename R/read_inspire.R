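## Readers for INSPIRE-style relational CSV tables.
##
## All tables use numeric timestamps: seconds on a per-patient clock (the
## source registry ships de-identified relative times). Readers convert to
## seconds from surgery start when an operations table is supplied.

#' Default column mappings and reader options
#'
#' The configuration names the CSV columns of each table and the reader
#' policies, and can be overridden wholesale or per key. Load a YAML file
#' with [load_config()].
#'
#' @return a nested list of configuration defaults.
#' @export
io_config <- function() {
  list(
    vitals = list(op_id = "op_id", time = "time", parameter = "parameter",
                  value = "value", map_parameter = "art_mbp",
                  map_min = 10, map_max = 200),
    operations = list(dialect = "columns",   # or "events"
                      op_id = "op_id", patient_id = "patient_id",
                      surgery_type = "surgery_type", emergency = "emergency",
                      surgery_start = "surgery_start", surgery_end = "surgery_end",
                      cpb_start = "cpb_start", cpb_stop = "cpb_stop",
                      event_time = "time", event_name = "event",
                      cpb_on = "cpb_on", cpb_off = "cpb_off"),
    labs = list(patient_id = "patient_id", time = "time",
                analyte = "analyte", value = "value",
                creatinine = "creatinine", unit = "mg/dl",
                scr_min = 0.1, scr_max = 30),
    baseline_policy = "most_recent_7d",
    max_gap_min = 5,
    thresholds = c(65, 75),
    interpolate_crossings = TRUE,
    missing_policy = "complete_case"       # or "impute"
  )
}

#' Load a YAML configuration file
#'
#' Reads a YAML file and merges it (recursively) over the defaults from
#' [io_config()], so a config file only needs to name the keys it changes.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- io_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_list_rec(cfg, user)
}

modify_list_rec <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- modify_list_rec(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

as_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    data.table::fread(x)
  } else data.table::as.data.table(x)
}

require_columns <- function(dt, cols, what) {
  miss <- setdiff(unlist(cols), names(dt))
  if (length(miss))
    stop(sprintf("%s table is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

#' Read long-format vitals into per-operation MAP series
#'
#' Reads a long-format vitals table (operation id, time, parameter name,
#' value), keeps the invasive-MAP parameter, applies plausibility filtering
#' (default 10–200 mmHg), deduplicates identical timestamps by averaging,
#' and returns one sorted [map_series] per operation together with a QC
#' report (`rows_in = rows_kept + rows_dropped` always holds; dedup events
#' are counted separately and do not drop rows from the balance).
#'
#' @param x path to a CSV file or a data.frame.
#' @param config configuration list (see [io_config()]); `config$vitals`
#'   names the columns, the MAP parameter label and plausibility bounds.
#' @param operations optional operations table (from [read_operations()]):
#'   when given, times are shifted to seconds from each operation's surgery
#'   start.
#' @return list with `series` (named list of [map_series], names are op
#'   ids) and `qc` (row counts: `rows_in`, `rows_kept`, `rows_dropped`,
#'   `dropped_nonnumeric`, `dropped_implausible`, `dedup_events`).
#' @export
read_vitals <- function(x, config = io_config(), operations = NULL) {
  cv <- config$vitals
  dt <- as_table(x)
  require_columns(dt, cv[c("op_id", "time", "parameter", "value")], "vitals")
  dt <- dt[, c(cv$op_id, cv$time, cv$parameter, cv$value), with = FALSE]
  data.table::setnames(dt, c("op_id", "time", "parameter", "value"))
  dt <- dt[parameter == cv$map_parameter]
  rows_in <- nrow(dt)
  dt[, value := suppressWarnings(as.numeric(value))]
  dt[, time := suppressWarnings(as.numeric(time))]
  bad_num <- !is.finite(dt$value) | !is.finite(dt$time)
  dropped_nonnumeric <- sum(bad_num)
  dt <- dt[!bad_num]
  implaus <- dt$value < cv$map_min | dt$value > cv$map_max
  dropped_implausible <- sum(implaus)
  dt <- dt[!implaus]

  if (!is.null(operations)) {
    ops <- operations[, c("op_id", "surgery_start")]
    dt <- merge(dt, data.table::as.data.table(ops), by = "op_id")
    dt[, time := time - surgery_start]
    dt[, surgery_start := NULL]
  }
  dropped_pre_surgery <- sum(dt$time < 0)
  dt <- dt[time >= 0]

  series <- lapply(split(dt, by = "op_id", keep.by = TRUE),
                   function(d) map_series(d$op_id[1L], d$time, d$value))
  names(series) <- vapply(series, function(s) as.character(s$op_id), character(1))
  dedup_events <- sum(vapply(series, function(s) s$n_dedup, integer(1)))
  rows_dropped <- dropped_nonnumeric + dropped_implausible + dropped_pre_surgery
  qc <- list(rows_in = rows_in,
             rows_kept = rows_in - rows_dropped,
             rows_dropped = rows_dropped,
             dropped_nonnumeric = dropped_nonnumeric,
             dropped_implausible = dropped_implausible,
             dropped_pre_surgery = dropped_pre_surgery,
             dedup_events = dedup_events)
  list(series = series, qc = qc)
}

#' Read the operations table
#'
#' Two dialects are supported: `"columns"`, where CPB start/stop are
#' columns of the operation row, and `"events"`, where CPB events live in a
#' separate long event table (`events` argument). Records whose CPB window
#' violates `surgery_start <= cpb_start < cpb_stop <= surgery_end` are
#' flagged ineligible with a reason code, never silently repaired.
#'
#' @param x path or data.frame of operations.
#' @param config configuration list.
#' @param events event table (path or data.frame) for the `"events"` dialect.
#' @return `data.table` with columns `op_id`, `patient_id`, `surgery_type`,
#'   `emergency`, `surgery_start`, `surgery_end`, `cpb_start`, `cpb_stop`
#'   (NA when absent), `valid_cpb` (logical), `reason` (`"no_cpb"`,
#'   `"invalid_cpb_window"`, or NA).
#' @export
read_operations <- function(x, config = io_config(), events = NULL) {
  co <- config$operations
  dt <- as_table(x)
  require_columns(dt, co[c("op_id", "patient_id", "surgery_start", "surgery_end")],
                  "operations")
  out <- data.table::data.table(
    op_id = dt[[co$op_id]],
    patient_id = dt[[co$patient_id]],
    surgery_type = if (co$surgery_type %in% names(dt)) as.character(dt[[co$surgery_type]]) else NA_character_,
    emergency = if (co$emergency %in% names(dt)) as.logical(dt[[co$emergency]]) else FALSE,
    surgery_start = as.numeric(dt[[co$surgery_start]]),
    surgery_end = as.numeric(dt[[co$surgery_end]]))

  if (identical(co$dialect, "events")) {
    if (is.null(events)) stop("events dialect requires an events table", call. = FALSE)
    ev <- as_table(events)
    require_columns(ev, co[c("op_id", "event_time", "event_name")], "events")
    on_t <- ev[get(co$event_name) == co$cpb_on,
               .(cpb_start = min(as.numeric(get(co$event_time)))), by = c(co$op_id)]
    off_t <- ev[get(co$event_name) == co$cpb_off,
                .(cpb_stop = max(as.numeric(get(co$event_time)))), by = c(co$op_id)]
    data.table::setnames(on_t, co$op_id, "op_id")
    data.table::setnames(off_t, co$op_id, "op_id")
    out <- merge(merge(out, on_t, by = "op_id", all.x = TRUE),
                 off_t, by = "op_id", all.x = TRUE)
  } else {
    out[, cpb_start := if (co$cpb_start %in% names(dt)) as.numeric(dt[[co$cpb_start]]) else NA_real_]
    out[, cpb_stop := if (co$cpb_stop %in% names(dt)) as.numeric(dt[[co$cpb_stop]]) else NA_real_]
  }

  out[, valid_cpb := !is.na(cpb_start) & !is.na(cpb_stop) &
        surgery_start <= cpb_start & cpb_start < cpb_stop & cpb_stop <= surgery_end]
  out[, reason := data.table::fifelse(
    is.na(cpb_start) | is.na(cpb_stop), "no_cpb",
    data.table::fifelse(valid_cpb, NA_character_, "invalid_cpb_window"))]
  out[]
}

#' Read long-format labs into per-patient creatinine series
#'
#' Keeps the configured analyte (creatinine), normalizes units to mg/dL
#' (`"umol/l"` divides by 88.4; `"mg/dl"` passes through; anything else is
#' a hard error — no silent unit guessing), applies plausibility bounds,
#' and returns sorted per-patient series.
#'
#' @param x path or data.frame, long format (patient id, time, analyte,
#'   value).
#' @param config configuration list; `config$labs$unit` names the source
#'   unit.
#' @return list with `labs` (a `data.table` of `patient_id`, `time`,
#'   `value` in mg/dL, sorted by patient and time) and `qc` (row counts).
#' @export
read_labs <- function(x, config = io_config()) {
  cl <- config$labs
  dt <- as_table(x)
  require_columns(dt, cl[c("patient_id", "time", "analyte", "value")], "labs")
  dt <- dt[, c(cl$patient_id, cl$time, cl$analyte, cl$value), with = FALSE]
  data.table::setnames(dt, c("patient_id", "time", "analyte", "value"))
  dt <- dt[analyte == cl$creatinine]
  rows_in <- nrow(dt)
  dt[, value := suppressWarnings(as.numeric(value))]
  dt[, time := suppressWarnings(as.numeric(time))]

  unit <- tolower(cl$unit)
  if (unit %in% c("umol/l", "µmol/l", "micromol/l")) {
    dt[, value := value / 88.4]
  } else if (unit != "mg/dl") {
    stop("unknown creatinine unit: ", cl$unit, call. = FALSE)
  }
  bad <- !is.finite(dt$value) | !is.finite(dt$time) |
    dt$value < cl$scr_min | dt$value > cl$scr_max
  dropped <- sum(bad)
  dt <- dt[!bad][order(patient_id, time)]
  list(labs = dt[, .(patient_id, time, value)],
       qc = list(rows_in = rows_in, rows_kept = rows_in - dropped,
                 rows_dropped = dropped))
}

#' Read the patient covariate table
#'
#' Wide-format, one row per patient, carrying the covariates of the
#' adjusted models: demographics, ASA status, eGFR stratum at admission,
#' EuroSCORE II, comorbidities, preoperative medications, intraoperative
#' totals and the postoperative CRRT indicator.
#'
#' @param x path or data.frame.
#' @return `data.table`, one row per patient.
#' @export
read_patients <- function(x) {
  dt <- as_table(x)
  if (!"patient_id" %in% names(dt))
    stop("patients table is missing required column(s): patient_id", call. = FALSE)
  if (anyDuplicated(dt$patient_id))
    stop("duplicate patient_id in patients table", call. = FALSE)
  # categorical columns stay character regardless of how the CSV parsed them
  for (v in intersect(c("sex", "asa_status", "egfr_stratum", "surgery_type"),
                      names(dt)))
    data.table::set(dt, j = v, value = as.character(dt[[v]]))
  dt[]
}

#' Write / read the analysis-ready cohort table
#'
#' Plain-CSV round trip for the cohort table; numeric columns survive
#' to full double precision (`fwrite` writes 15 significant digits).
#'
#' @param cohort a cohort `data.table` (from [build_cohort()]).
#' @param path output CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the `data.table`.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) data.table::fread(path)

#' Write a QC / attrition report as JSON
#'
#' @param report a named list of counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
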