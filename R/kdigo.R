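## KDIGO creatinine-criteria adjudication of cardiac surgery-associated
## acute kidney injury (CSA-AKI), all stages, within a 7-day postoperative
## horizon. Urine-output criteria are excluded by construction.

DAY_S <- 86400

#' Baseline serum creatinine
#'
#' Selects the baseline creatinine from preoperative labs under a stated
#' policy. Times are seconds relative to surgery start (preoperative values
#' have `t < 0`).
#'
#' @param t numeric times (s from surgery start) of creatinine measurements.
#' @param scr creatinine values, mg/dL.
#' @param policy one of `"most_recent_7d"` (default: most recent value in
#'   the 7 days before surgery), `"min_7d"` (minimum in the 7 days before),
#'   `"most_recent_30d"`.
#' @return baseline creatinine in mg/dL, or `NA_real_` when no qualifying
#'   preoperative value exists (caller flags the patient `no_baseline`).
#' @export
baseline_creatinine <- function(t, scr,
                                policy = c("most_recent_7d", "min_7d",
                                           "most_recent_30d")) {
  policy <- match.arg(policy)
  lookback <- if (policy == "most_recent_30d") 30 * DAY_S else 7 * DAY_S
  pre <- t < 0 & t >= -lookback & is.finite(scr)
  if (!any(pre)) return(NA_real_)
  tp <- t[pre]; vp <- scr[pre]
  switch(policy,
         most_recent_7d  = vp[which.max(tp)],
         most_recent_30d = vp[which.max(tp)],
         min_7d          = min(vp))
}

#' KDIGO creatinine staging of postoperative AKI
#'
#' Adjudicates AKI by the KDIGO serum-creatinine criteria within a 7-day
#' postoperative horizon. AKI is present when (a) any postoperative
#' creatinine rises by at least 0.3 mg/dL above any prior measured value
#' (baseline included) within a rolling 48-hour window, or (b) any value
#' reaches at least 1.5 times baseline within the horizon, or (c) renal
#' replacement therapy is initiated within the horizon. Stages: 1 for a
#' 1.5–1.9-fold rise or the 0.3 mg/dL criterion; 2 for 2.0–2.9-fold;
#' 3 for a rise of at least 3.0-fold, creatinine of at least 4.0 mg/dL with
#' a qualifying acute rise, or RRT. The reported stage is the maximum
#' attained in the horizon; `onset_t` is the first time any criterion holds.
#'
#' @param t numeric lab times, seconds from surgery start (postoperative
#'   values have `t > 0`; values after the horizon are ignored).
#' @param scr creatinine values, mg/dL, same length as `t`.
#' @param baseline_scr baseline creatinine, mg/dL (> 0).
#' @param rrt logical: renal replacement therapy initiated within the
#'   horizon. Forces stage 3.
#' @param horizon_days adjudication horizon, days after surgery (default 7).
#' @return list of class `aki_result`: `aki` (logical), `stage` (0–3),
#'   `onset_t` (s; `NA` when no creatinine criterion fires), `criterion`
#'   (`"abs_increase_48h"`, `"relative_increase_7d"`, `"scr_ge_4"`,
#'   `"rrt"`, or `NA`; the first entry criterion met, except that
#'   `"scr_ge_4"` or `"rrt"` is reported when it alone determines stage 3),
#'   `baseline_scr`, `flag`
#'   (`"no_postop_labs"` when the postoperative series is empty).
#' @export
kdigo_stage <- function(t, scr, baseline_scr, rrt = FALSE, horizon_days = 7) {
  stopifnot(is.finite(baseline_scr), baseline_scr > 0)
  horizon <- horizon_days * DAY_S
  post <- which(t > 0 & t <= horizon & is.finite(scr))
  ord <- post[order(t[post])]
  tp <- t[ord]; vp <- scr[ord]

  res <- list(aki = FALSE, stage = 0L, onset_t = NA_real_,
              criterion = NA_character_, baseline_scr = baseline_scr,
              flag = NA_character_)
  if (!length(tp)) {
    res$flag <- "no_postop_labs"
    if (rrt) { res$aki <- TRUE; res$stage <- 3L; res$criterion <- "rrt" }
    class(res) <- "aki_result"
    return(res)
  }

  # anchors for the rolling 48-h absolute-increase criterion: the baseline
  # (taken as available at t = 0) and every prior postoperative value
  anchor_t <- c(0, tp); anchor_v <- c(baseline_scr, vp)
  abs_hit <- vapply(seq_along(tp), function(i) {
    ok <- anchor_t <= tp[i] & (tp[i] - anchor_t) <= 2 * DAY_S &
      seq_along(anchor_t) <= i            # anchors strictly prior or baseline
    any(vp[i] - anchor_v[ok] >= 0.3 - 1e-12)
  }, logical(1))
  rel_hit <- vp >= 1.5 * baseline_scr - 1e-12

  entry <- abs_hit | rel_hit
  if (any(entry)) {
    first <- which(entry)[1L]
    res$aki <- TRUE
    res$onset_t <- tp[first]
    res$criterion <- if (abs_hit[first]) "abs_increase_48h" else "relative_increase_7d"
    ratio <- max(vp) / baseline_scr
    stage <- 1L
    if (ratio >= 2 - 1e-12) stage <- 2L
    if (ratio >= 3 - 1e-12) stage <- 3L
    # SCr >= 4.0 counts as stage 3 only alongside a qualifying acute rise
    # (an entry criterion), guarding against chronic elevation. When it is
    # what lifts the stage to 3, it is reported as the criterion.
    if (any(vp >= 4 - 1e-12) && stage < 3L) {
      stage <- 3L
      res$criterion <- "scr_ge_4"
    }
    res$stage <- stage
  }
  if (rrt) {
    res$aki <- TRUE
    res$stage <- 3L
    if (is.na(res$criterion)) res$criterion <- "rrt"
  }
  class(res) <- "aki_result"
  res
}

#' @export
print.aki_result <- function(x, ...) {
  cat(sprintf("<aki_result> aki=%s stage=%d criterion=%s onset=%s baseline=%.2f mg/dL%s\n",
              x$aki, x$stage, x$criterion,
              if (is.na(x$onset_t)) "NA" else sprintf("%.1f h", x$onset_t / 3600),
              x$baseline_scr,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' CRRT secondary outcome
#'
#' Passthrough of the continuous renal replacement therapy indicator for
#' the postoperative hospital stay (no 7-day horizon). A missing indicator
#' is treated as `FALSE`; callers should log the count of missing values.
#'
#' @param crrt_postop logical vector (may contain `NA`).
#' @return logical vector with `NA` mapped to `FALSE`.
#' @export
crrt_outcome <- function(crrt_postop) {
  out <- as.logical(crrt_postop)
  out[is.na(out)] <- FALSE
  out
}
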