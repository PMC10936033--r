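## Statistical models: rank-sum comparisons, crude and adjusted logistic
## regressions with Wald CIs, delta-method predicted-probability curves,
## and the sensitivity/subgroup analysis suite.

#' Wilcoxon–Mann–Whitney rank-sum test
#'
#' Two-sample, two-sided rank-sum test. For small samples (both groups at
#' most `exact_max`) the null distribution of U is enumerated exhaustively
#' over all group assignments of the pooled (tied) ranks; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max largest group size for exact enumeration (default 10).
#' @return list with `statistic` (U for `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("rank_sum_test requires both groups non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(statistic = U, p_value = p, method = "exact_enumeration"))
  }

  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = U, p_value = 1, method = "normal_approx"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)   # continuity correction toward the mean
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = U, p_value = p, method = "normal_approx")
}

#' Specify a logistic model
#'
#' @param outcome outcome column (`"aki"` or `"crrt"`).
#' @param exposure exposure column (default `"twa65_cpb"`).
#' @param covariates adjustment covariates (default [model_covariates()];
#'   use `character(0)` for a crude model).
#' @param subgroup optional named filter, e.g. `list(hypertension = TRUE)`.
#' @return a `model_spec` list.
#' @export
model_spec <- function(outcome = "aki", exposure = "twa65_cpb",
                       covariates = model_covariates(), subgroup = NULL) {
  if (exposure %in% covariates)
    stop("exposure must not be duplicated among covariates", call. = FALSE)
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, subgroup = subgroup),
            class = "model_spec")
}

prepare_model_frame <- function(cohort, spec) {
  dt <- data.table::as.data.table(cohort)
  for (nm in names(spec$subgroup)) dt <- dt[dt[[nm]] == spec$subgroup[[nm]]]
  need <- c(spec$outcome, spec$exposure, spec$covariates)
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- as.data.frame(dt[, need, with = FALSE])
  # reference-cell dummy coding with fixed reference levels: first level in
  # sorted order, so runs are reproducible across input orderings
  for (v in need[-1]) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]], levels = sort(unique(df[[v]])))
    if (is.logical(df[[v]])) df[[v]] <- as.numeric(df[[v]])
  }
  df[[spec$outcome]] <- as.numeric(df[[spec$outcome]])
  df
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression (IRLS; converged when the
#' relative deviance change falls below 1e-8, at most 100 iterations).
#' Returns per-term odds ratios with 95% Wald confidence intervals
#' (`exp(b +/- 1.96 se)`) and Wald p-values. Continuous terms are per-unit
#' (per mmHg for the TWA exposure). Degenerate outcomes, rank-deficient
#' designs and (quasi-)separation are surfaced, never silently absorbed.
#'
#' @param cohort cohort table.
#' @param spec a [model_spec()].
#' @return object of class `model_fit`: `coefficients`, `vcov`, `table`
#'   (term, estimate, se, or, ci_lo, ci_hi, p), `n`, `n_events`,
#'   `converged`, `flags`, and the underlying `glm` object (`fit`).
#' @export
fit_logistic <- function(cohort, spec) {
  df <- prepare_model_frame(cohort, spec)
  y <- df[[spec$outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("degenerate_outcome: outcome does not take both values", call. = FALSE)

  rhs <- paste(c(spec$exposure, spec$covariates), collapse = " + ")
  fml <- stats::as.formula(paste(spec$outcome, "~", rhs))
  X <- stats::model.matrix(fml, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  fit <- stats::glm(fml, data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  flags <- character(0)
  if (!fit$converged) flags <- c(flags, "not_converged")
  mu <- stats::fitted(fit)
  if (any(mu > 1 - 1e-8) || any(mu < 1e-8) || any(abs(stats::coef(fit)) > 15))
    flags <- c(flags, "possible_separation")

  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  tab <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                    or = exp(unname(b)),
                    ci_lo = exp(unname(b) - 1.96 * unname(se)),
                    ci_hi = exp(unname(b) + 1.96 * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
                    row.names = NULL)
  structure(list(coefficients = b, vcov = V, table = tab,
                 n = nrow(df), n_events = sum(y == 1),
                 converged = fit$converged && !length(flags),
                 flags = flags, spec = spec, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<model_fit> %s ~ %s + %d covariate(s): n=%d, events=%d%s\n",
              x$spec$outcome, x$spec$exposure, length(x$spec$covariates),
              x$n, x$n_events,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  i <- x$table$term == x$spec$exposure
  cat(sprintf("  exposure OR %.*f (95%% CI %.*f-%.*f), p=%.2g\n",
              digits, x$table$or[i], digits, x$table$ci_lo[i],
              digits, x$table$ci_hi[i], x$table$p[i]))
  invisible(x)
}

#' Extract the exposure odds ratio from a fit
#'
#' @param fit a `model_fit`.
#' @return one-row data.frame with `or`, `ci_lo`, `ci_hi`, `p`.
#' @export
exposure_or <- function(fit) {
  i <- fit$table$term == fit$spec$exposure
  fit$table[i, c("or", "ci_lo", "ci_hi", "p")]
}

#' Predicted-probability curve with delta-method confidence band
#'
#' Predicted probability of the outcome over a grid of exposure values,
#' with a pointwise 95% band obtained by the delta method on the linear
#' predictor and transformed through the inverse logit (so the band always
#' lies in \[0, 1\]). Covariates are held at the cohort mean for continuous
#' terms and at the reference level for categoricals, unless a `profile`
#' overrides specific columns.
#'
#' @param fit a converged `model_fit`.
#' @param grid numeric vector of exposure values (default: 100 points over
#'   the observed exposure range).
#' @param profile optional named list of covariate values to hold fixed.
#' @return data.frame with `exposure`, `p_hat`, `lo`, `hi`.
#' @export
predicted_probability_curve <- function(fit, grid = NULL, profile = NULL) {
  mf <- fit$fit$model
  expo <- fit$spec$exposure
  if (is.null(grid))
    grid <- seq(min(mf[[expo]]), max(mf[[expo]]), length.out = 100)
  if (any(grid < min(mf[[expo]]) | grid > max(mf[[expo]])))
    warning("grid extends outside the observed exposure range")

  nd <- mf[rep(1L, length(grid)), , drop = FALSE]
  for (v in setdiff(names(mf), c(fit$spec$outcome, expo))) {
    nd[[v]] <- if (is.numeric(mf[[v]])) mean(mf[[v]]) else
      factor(levels(mf[[v]])[1L], levels = levels(mf[[v]]))
  }
  nd[[expo]] <- grid
  for (v in names(profile)) nd[[v]] <- profile[[v]]

  X <- stats::model.matrix(stats::delete.response(stats::terms(fit$fit)), nd)
  lp <- drop(X %*% fit$coefficients)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  data.frame(exposure = grid,
             p_hat = stats::plogis(lp),
             lo = stats::plogis(lp - 1.96 * se),
             hi = stats::plogis(lp + 1.96 * se))
}

#' Descriptive comparison table with rank-sum p-values
#'
#' Medians (25th–75th percentile) for continuous variables and counts
#' (percent) for binaries/categoricals, split by a binary grouping column,
#' with two-sided rank-sum p-values.
#'
#' @param cohort cohort table.
#' @param by grouping column (default `"aki"`).
#' @param vars variables to summarize (default: exposures + model
#'   covariates present in the cohort).
#' @return data.frame, one row per variable (categoricals expand per level).
#' @export
descriptive_table <- function(cohort, by = "aki", vars = NULL) {
  dt <- data.table::as.data.table(cohort)
  if (is.null(vars))
    vars <- intersect(c("twa65_cpb", "twa75_cpb", model_covariates()), names(dt))
  g <- as.logical(dt[[by]])
  fmt_cont <- function(v) sprintf("%.2f (%.2f-%.2f)", stats::median(v),
                                  stats::quantile(v, .25), stats::quantile(v, .75))
  fmt_bin <- function(v) sprintf("%d (%.1f%%)", sum(v), 100 * mean(v))
  rows <- lapply(vars, function(nm) {
    v <- dt[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      data.frame(variable = paste0(nm, "=", levels(v)),
                 group1 = vapply(levels(v), function(l) fmt_bin(v[g] == l), ""),
                 group0 = vapply(levels(v), function(l) fmt_bin(v[!g] == l), ""),
                 p = vapply(levels(v), function(l)
                   rank_sum_test(as.numeric(v[g] == l), as.numeric(v[!g] == l))$p_value,
                   0))
    } else {
      vn <- as.numeric(v)
      binary <- all(vn %in% c(0, 1))
      data.frame(variable = nm,
                 group1 = if (binary) fmt_bin(vn[g]) else fmt_cont(vn[g]),
                 group0 = if (binary) fmt_bin(vn[!g]) else fmt_cont(vn[!g]),
                 p = rank_sum_test(vn[g], vn[!g])$p_value)
    }
  })
  out <- do.call(rbind, rows)
  names(out) <- c("variable", paste0(by, "_yes"), paste0(by, "_no"), "p_rank_sum")
  rownames(out) <- NULL
  out
}

#' Run the full association analysis suite
#'
#' Produces (i) a descriptive comparison by AKI status with rank-sum
#' p-values; (ii) crude and covariate-adjusted odds ratios for the AKI and
#' CRRT outcomes; (iii) the 75-mmHg threshold sensitivity analysis (same
#' covariates, exposures recomputed at 75 mmHg); (iv) the hypertension
#' subgroup analysis (covariate set minus hypertension); and (v) the
#' predicted-probability curve for AKI. Any flagged fit is reported in the
#' bundle, never hidden.
#'
#' @param cohort analysis-ready cohort table.
#' @param out_dir optional directory: writes the tables as CSV, the curve
#'   and an example exposure trace as PNG, and a JSON model dump.
#' @param series optional named list of [map_series] (for the exposure
#'   trace figure).
#' @param windows optional named list of [analysis_window] matching
#'   `series` (CPB windows for the figure).
#' @return list with `table_s1`, `table_s2`, `table_s3`, `table_s4`,
#'   `prob_curve`, `fits` (all model_fit objects), `all_converged`.
#' @export
run_analysis_suite <- function(cohort, out_dir = NULL, series = NULL,
                               windows = NULL) {
  covs <- intersect(model_covariates(), names(cohort))
  fits <- list(
    aki_crude     = fit_logistic(cohort, model_spec("aki", "twa65_cpb", character(0))),
    aki_adjusted  = fit_logistic(cohort, model_spec("aki", "twa65_cpb", covs)),
    crrt_crude    = fit_logistic(cohort, model_spec("crrt", "twa65_cpb", character(0))),
    crrt_adjusted = fit_logistic(cohort, model_spec("crrt", "twa65_cpb", covs)),
    aki_75   = fit_logistic(cohort, model_spec("aki", "twa75_cpb",
                                               setdiff(covs, "twa65_postcpb"))),
    crrt_75  = fit_logistic(cohort, model_spec("crrt", "twa75_cpb",
                                               setdiff(covs, "twa65_postcpb"))),
    aki_htn  = fit_logistic(cohort, model_spec("aki", "twa65_cpb",
                                               setdiff(covs, "hypertension"),
                                               subgroup = list(hypertension = TRUE))),
    aki_no_htn = fit_logistic(cohort, model_spec("aki", "twa65_cpb",
                                                 setdiff(covs, "hypertension"),
                                                 subgroup = list(hypertension = FALSE))))

  or_row <- function(nm) cbind(model = nm, n = fits[[nm]]$n,
                               n_events = fits[[nm]]$n_events,
                               exposure_or(fits[[nm]]),
                               converged = fits[[nm]]$converged)
  bundle <- list(
    table_s1 = descriptive_table(cohort, by = "aki"),
    table_s2 = do.call(rbind, lapply(c("aki_crude", "aki_adjusted",
                                       "crrt_crude", "crrt_adjusted"), or_row)),
    table_s3 = do.call(rbind, lapply(c("aki_75", "crrt_75"), or_row)),
    table_s4 = do.call(rbind, lapply(c("aki_htn", "aki_no_htn"), or_row)),
    prob_curve = predicted_probability_curve(fits$aki_adjusted),
    fits = fits,
    all_converged = all(vapply(fits, function(f) f$converged, logical(1))))

  if (!is.null(out_dir)) write_analysis_bundle(bundle, out_dir, series, windows)
  bundle
}

write_analysis_bundle <- function(bundle, out_dir, series = NULL, windows = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("table_s1", "table_s2", "table_s3", "table_s4", "prob_curve"))
    data.table::fwrite(bundle[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  dump <- lapply(bundle$fits, function(f)
    list(coefficients = as.list(f$coefficients),
         vcov = unclass(f$vcov), n = f$n, n_events = f$n_events,
         converged = f$converged, flags = f$flags))
  jsonlite::write_json(dump, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  try({
    grDevices::png(file.path(out_dir, "fig1b_predicted_probability.png"),
                   width = 800, height = 600)
    plot_probability_curve(bundle$prob_curve)
    grDevices::dev.off()
    if (!is.null(series) && length(series)) {
      grDevices::png(file.path(out_dir, "fig1a_map_trace.png"),
                     width = 800, height = 600)
      plot_map_trace(series[[1L]],
                     if (!is.null(windows)) windows[[1L]] else NULL)
      grDevices::dev.off()
    }
  }, silent = TRUE)
  invisible(out_dir)
}
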