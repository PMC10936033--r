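## End-to-end cohort pipeline: tables in, analysis-ready cohort + reports out.

#' Run the full cohort pipeline
#'
#' Reads (or accepts in-memory) the four relational tables, applies
#' eligibility, computes hypotension exposures at every configured
#' threshold for the CPB and post-CPB windows, adjudicates AKI by the
#' KDIGO creatinine criteria, and assembles the analysis-ready cohort.
#'
#' The RRT flag passed to the adjudicator is CRRT initiated within the
#' 7-day horizon: `crrt_postop` restricted by the optional
#' `crrt_start_day` column when present (CRRT started later than day 7
#' keeps the CRRT secondary outcome but does not force AKI stage 3).
#'
#' @param vitals,operations,labs,patients paths or data.frames.
#' @param config configuration list from [io_config()] / [load_config()].
#' @param events optional CPB event table for the `"events"` dialect.
#' @return list with `cohort`, `attrition`, `qc` (reader QC reports).
#' @export
run_cohort_pipeline <- function(vitals, operations, labs, patients,
                                config = io_config(), events = NULL) {
  ops <- read_operations(operations, config, events = events)
  vit <- read_vitals(vitals, config, operations = ops)
  lab <- read_labs(labs, config)
  pat <- read_patients(patients)

  elig <- apply_eligibility(ops, vit$series, config$max_gap_min)
  el <- elig$eligible

  thresholds <- config$thresholds
  expo <- data.table::rbindlist(lapply(seq_len(nrow(el)), function(i) {
    s <- vit$series[[as.character(el$op_id[i])]]
    t0 <- el$surgery_start[i]
    win_cpb <- analysis_window("cpb", el$cpb_start[i] - t0, el$cpb_stop[i] - t0)
    row <- list(op_id = el$op_id[i])
    post_ok <- el$cpb_stop[i] < el$surgery_end[i]
    if (post_ok)
      win_post <- analysis_window("post_cpb", el$cpb_stop[i] - t0,
                                  el$surgery_end[i] - t0)
    for (T in thresholds) {
      row[[sprintf("twa%d_cpb", T)]] <-
        twa_below(s, win_cpb, T, config$interpolate_crossings)$twa_below
      row[[sprintf("twa%d_postcpb", T)]] <- if (post_ok)
        tryCatch(twa_below(s, win_post, T, config$interpolate_crossings)$twa_below,
                 error = function(e) NA_real_) else NA_real_
    }
    row
  }))

  # outcome adjudication per eligible patient
  lab_by_pat <- split(lab$labs, by = "patient_id", keep.by = FALSE)
  pat_dt <- data.table::as.data.table(pat)
  aki <- data.table::rbindlist(lapply(seq_len(nrow(el)), function(i) {
    pid <- el$patient_id[i]
    t0 <- el$surgery_start[i]
    pl <- lab_by_pat[[as.character(pid)]]
    p <- pat_dt[patient_id == pid]
    crrt <- isTRUE(crrt_outcome(if (nrow(p)) p$crrt_postop[1L] else NA))
    rrt_7d <- crrt && (!"crrt_start_day" %in% names(p) ||
                         is.na(p$crrt_start_day[1L]) || p$crrt_start_day[1L] <= 7)
    if (is.null(pl) || !nrow(pl)) {
      base <- NA_real_
    } else {
      base <- baseline_creatinine(pl$time - t0, pl$value, config$baseline_policy)
    }
    if (is.na(base)) {
      return(list(patient_id = pid, aki = NA, aki_stage = NA_integer_,
                  aki_criterion = NA_character_, baseline_scr = NA_real_,
                  aki_flag = "no_baseline"))
    }
    res <- kdigo_stage(pl$time - t0, pl$value, base, rrt = rrt_7d)
    list(patient_id = pid, aki = res$aki, aki_stage = res$stage,
         aki_criterion = res$criterion, baseline_scr = res$baseline_scr,
         aki_flag = res$flag)
  }))

  built <- build_cohort(el, expo, aki, pat, config$missing_policy)
  attrition <- c(elig$attrition, built$attrition)
  attrition$n_eligible <- nrow(built$cohort)
  list(cohort = built$cohort, attrition = attrition,
       qc = list(vitals = vit$qc, labs = lab$qc))
}
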