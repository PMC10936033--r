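## Cohort assembly: eligibility, exposure computation per window, outcome
## adjudication, covariate join, attrition accounting.

# covariates entering the adjusted models, in reporting order
MODEL_COVARIATES <- c(
  "age", "sex", "weight", "surgery_type", "emergency", "asa_status",
  "egfr_stratum", "euroscore2", "diabetes", "heart_failure", "hypertension",
  "copd", "pvd", "beta_blocker", "raas_blockade", "calcium_antagonist",
  "vasopressor_dose", "fluid_balance", "twa65_postcpb", "cpb_time",
  "prbc_units")

#' Covariates of the adjusted models
#'
#' Names, in reporting order, of the covariates the multivariable models
#' adjust for (besides the exposure): age, sex, weight, type of surgery,
#' emergency surgery, ASA status, eGFR strata at admission, EuroSCORE II,
#' diabetes, heart failure, hypertension, COPD, peripheral vascular
#' disease, preoperative beta-blocker / RAAS blockade / calcium-antagonist
#' use, total vasopressor-inotrope dose, fluid balance, TWA-MAP under
#' 65 mmHg during the post-CPB period, CPB time, and pRBC units transfused.
#'
#' @return character vector of cohort column names.
#' @export
model_covariates <- function() MODEL_COVARIATES

#' Apply eligibility rules to operations
#'
#' Keeps operations that (i) have a valid CPB window, (ii) pass the
#' sampling-resolution check on the CPB window (default: no gap above
#' 5 minutes), and (iii) are the patient's first qualifying cardiac
#' surgery (reoperations are excluded to avoid correlated observations).
#' Exclusions are data, not errors; every input operation is accounted for
#' in the attrition report (`n_input = n_eligible + sum of exclusions`).
#'
#' @param operations operations `data.table` from [read_operations()].
#' @param series named list of [map_series] from [read_vitals()].
#' @param max_gap_min resolution limit in minutes (default 5).
#' @return list with `eligible` (operations rows that pass, plus
#'   `max_gap`) and `attrition` (named integer counts).
#' @export
apply_eligibility <- function(operations, series, max_gap_min = 5) {
  ops <- data.table::as.data.table(operations)
  n_input <- nrow(ops)
  reasons <- character(n_input)
  max_gaps <- rep(NA_real_, n_input)

  for (i in seq_len(n_input)) {
    if (!is.na(ops$reason[i])) { reasons[i] <- ops$reason[i]; next }
    s <- series[[as.character(ops$op_id[i])]]
    win <- analysis_window("cpb", ops$cpb_start[i] - ops$surgery_start[i],
                           ops$cpb_stop[i] - ops$surgery_start[i])
    if (is.null(s)) { reasons[i] <- "insufficient_resolution"; next }
    rc <- resolution_check(s, win, max_gap_min)
    max_gaps[i] <- rc$max_gap
    if (!rc$ok) reasons[i] <- "insufficient_resolution"
  }
  ops[, reason := data.table::fifelse(reasons == "", NA_character_, reasons)]
  ops[, max_gap := max_gaps]

  # first qualifying operation per patient, by surgery start
  cand <- ops[is.na(reason)][order(patient_id, surgery_start)]
  dup <- duplicated(cand$patient_id)
  ops[op_id %in% cand$op_id[dup], reason := "reoperation"]

  eligible <- ops[is.na(reason)]
  excl <- table(ops$reason[!is.na(ops$reason)])
  attrition <- c(list(n_input = n_input, n_eligible = nrow(eligible)),
                 as.list(stats::setNames(as.integer(excl), names(excl))))
  list(eligible = eligible, attrition = attrition)
}

#' Total vasopressor-inotrope dose in norepinephrine equivalents
#'
#' Weighted sum of per-drug intraoperative totals. The equivalence weights
#' are explicit configuration because no standard aggregation is mandated
#' by the data source; defaults: norepinephrine 1, epinephrine 1,
#' dopamine 0.01, dobutamine 0.01, vasopressin 2.5 (per unit),
#' phenylephrine 0.1.
#'
#' @param drug character vector of drug names.
#' @param dose numeric vector of per-drug totals (same length).
#' @param weights named numeric vector of equivalence weights.
#' @return scalar total equivalent dose. A drug absent from the weight
#'   table is a hard error naming the drug.
#' @export
vasopressor_dose_total <- function(drug, dose,
                                   weights = c(norepinephrine = 1, epinephrine = 1,
                                               dopamine = 0.01, dobutamine = 0.01,
                                               vasopressin = 2.5, phenylephrine = 0.1)) {
  if (!length(drug)) return(0)
  stopifnot(length(drug) == length(dose))
  unknown <- setdiff(unique(drug), names(weights))
  if (length(unknown))
    stop("no equivalence weight for drug(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(weights[drug] * dose)
}

#' Estimated GFR (CKD-EPI 2009) and KDIGO eGFR strata
#'
#' `egfr_ckdepi()` implements the 2009 CKD-EPI creatinine equation
#' (race-free usage); `egfr_stratum()` maps eGFR onto the KDIGO G strata
#' with cutpoints 90/60/45/30/15 (G1 ... G5). These helpers exist for
#' sources that ship creatinine but no precomputed stratum; when the
#' patients table carries a stratum it is consumed as-is.
#'
#' @param scr serum creatinine, mg/dL.
#' @param age years.
#' @param sex `"f"`/`"m"` (case-insensitive).
#' @param egfr estimated GFR in mL/min/1.73m2.
#' @return numeric eGFR, or character stratum `"G1"`–`"G5"`.
#' @export
egfr_ckdepi <- function(scr, age, sex) {
  female <- tolower(substr(as.character(sex), 1, 1)) == "f"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1)
}

#' @rdname egfr_ckdepi
#' @export
egfr_stratum <- function(egfr) {
  cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf),
      labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"), right = FALSE)
}

#' Assemble the analysis-ready cohort table
#'
#' Inner-joins eligible operations with exposure summaries, adjudicated
#' outcomes and patient covariates into one row per patient, then applies
#' the missing-covariate policy (default complete-case with logged
#' counts).
#'
#' @param eligible eligible operations (from [apply_eligibility()]).
#' @param exposures `data.table` keyed by `op_id` with columns
#'   `twa65_cpb`, `twa65_postcpb`, `twa75_cpb`, `twa75_postcpb`.
#' @param aki `data.table` keyed by `patient_id` with `aki`, `aki_stage`,
#'   `aki_criterion`, `baseline_scr`, `aki_flag`.
#' @param patients patient covariate table (from [read_patients()]).
#' @param missing_policy `"complete_case"` (drop rows with missing model
#'   covariates) or `"impute"` (median for numerics, mode for
#'   categoricals).
#' @return list with `cohort` (`data.table`) and `attrition` additions
#'   (named counts: `no_baseline`, `no_postop_labs` if excluded,
#'   `missing_covariates`).
#' @export
build_cohort <- function(eligible, exposures, aki, patients,
                         missing_policy = c("complete_case", "impute")) {
  missing_policy <- match.arg(missing_policy)
  el <- data.table::as.data.table(eligible)
  if (anyDuplicated(el$patient_id) || anyDuplicated(el$op_id))
    stop("key collision: duplicate patient or operation ids in eligible set",
         call. = FALSE)
  co <- el[, .(op_id, patient_id, surgery_type, emergency,
               cpb_time = (cpb_stop - cpb_start) / 60)]
  co <- merge(co, data.table::as.data.table(exposures), by = "op_id")
  co <- merge(co, data.table::as.data.table(aki), by = "patient_id")
  co <- merge(co, data.table::as.data.table(patients), by = "patient_id")
  if ("crrt_postop" %in% names(co)) co[, crrt := crrt_outcome(crrt_postop)]

  attr_add <- list()
  n0 <- nrow(co)
  no_base <- is.na(co$baseline_scr)
  if (any(no_base)) {
    attr_add$no_baseline <- sum(no_base)
    co <- co[!no_base]
  }

  covs <- intersect(MODEL_COVARIATES, names(co))
  if (missing_policy == "complete_case") {
    ok <- stats::complete.cases(co[, covs, with = FALSE])
    if (any(!ok)) attr_add$missing_covariates <- sum(!ok)
    co <- co[ok]
  } else {
    for (v in covs) {
      miss <- is.na(co[[v]])
      if (!any(miss)) next
      fill <- if (is.numeric(co[[v]])) stats::median(co[[v]], na.rm = TRUE)
              else names(sort(table(co[[v]]), decreasing = TRUE))[1L]
      data.table::set(co, which(miss), v, fill)
    }
  }
  list(cohort = co[], attrition = attr_add)
}
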