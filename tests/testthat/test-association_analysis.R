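# Rank-sum test, logistic fits, predicted probabilities, analysis suite.

test_that("rank-sum exact enumeration matches hand-derived cases", {
  # complete separation of n=3 vs 3: U = 0, exact two-sided p = 2/20
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact_enumeration")
  # identical samples -> p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("rank-sum agrees with the reference implementation", {
  set.seed(31)
  # exact branch vs wilcox.test exact (no ties)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    expect_equal(rank_sum_test(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # normal-approx branch with ties and continuity correction
  for (i in 1:20) {
    x <- sample(1:8, 40, TRUE); y <- sample(2:9, 35, TRUE)
    expect_equal(rank_sum_test(x, y)$p_value,
                 suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum detects a 0.5-SD shift at n=200 in >= 90% of runs", {
  set.seed(77)
  hits <- mean(replicate(500, {
    rank_sum_test(rnorm(200), rnorm(200, 0.5))$p_value < 0.05
  }))
  expect_gte(hits, 0.9)
})

test_that("2x2 logistic fit equals the cross-product odds ratio", {
  co <- cohort_2x2(10, 5, 5, 10)
  fit <- fit_logistic(co, model_spec("aki", "exposure", character(0)))
  expect_equal(exposure_or(fit)$or, 4.0, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["exposure"]), log(4), tolerance = 1e-6)
  expect_equal(fit$n, 30)
  expect_equal(fit$n_events, 15)
  set.seed(41)
  for (i in 1:10) {
    k <- sample(3:30, 4, TRUE)
    f <- fit_logistic(cohort_2x2(k[1], k[2], k[3], k[4]),
                      model_spec("aki", "exposure", character(0)))
    expect_equal(exposure_or(f)$or, k[1] * k[4] / (k[2] * k[3]),
                 tolerance = 1e-6)
  }
})

test_that("degenerate, collinear and duplicated-exposure designs are refused", {
  co <- cohort_2x2(10, 5, 5, 10)
  co$aki <- FALSE
  expect_error(fit_logistic(co, model_spec("aki", "exposure", character(0))),
               "degenerate_outcome")
  co2 <- cohort_2x2(10, 5, 5, 10)
  co2$copy_of_exposure <- co2$exposure
  expect_error(fit_logistic(co2, model_spec("aki", "exposure", "copy_of_exposure")),
               "collinear.*copy_of_exposure")
  expect_error(model_spec("aki", "exposure", c("exposure", "age")),
               "duplicated")
})

test_that("separation is flagged, not silently reported", {
  co <- cohort_2x2(12, 0, 0, 12)  # perfect separation
  fit <- suppressWarnings(
    fit_logistic(co, model_spec("aki", "exposure", character(0))))
  expect_false(fit$converged)
  expect_true("possible_separation" %in% fit$flags)
})

test_that("null-exposure CIs cover 1.0 at the nominal rate", {
  set.seed(55)
  covered <- replicate(400, {
    n <- 2000
    z <- rnorm(n)
    x <- rlnorm(n, 1, 0.8)
    p <- plogis(-0.8 + 0.3 * z)       # exposure truly null
    co <- data.table::data.table(aki = runif(n) < p, twa = x, z = z)
    or <- exposure_or(fit_logistic(co, model_spec("aki", "twa", "z")))
    or$ci_lo <= 1 && 1 <= or$ci_hi
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("crude and adjusted ORs agree when confounding is absent", {
  set.seed(66)
  n <- 6000
  x <- rlnorm(n, 1, 0.8)
  z <- rnorm(n)                        # independent of x -> no confounding
  p <- plogis(-1.2 + log(1.3) * x + 0.2 * z)
  co <- data.table::data.table(aki = runif(n) < p, twa = x, z = z)
  crude <- exposure_or(fit_logistic(co, model_spec("aki", "twa", character(0))))
  adj <- exposure_or(fit_logistic(co, model_spec("aki", "twa", "z")))
  expect_equal(log(crude$or), log(adj$or), tolerance = 0.05)
})

test_that("predicted probability curve respects [0,1] and its constructions", {
  # intercept-only: p = 0.5 everywhere with a symmetric band
  co <- data.table::data.table(aki = rep(c(TRUE, FALSE), 50),
                               twa = rep(c(0, 1), 50))
  fit <- fit_logistic(co, model_spec("aki", "twa", character(0)))
  cv <- predicted_probability_curve(fit, grid = c(0.25, 0.5, 0.75))
  expect_true(all(cv$lo >= 0 & cv$hi <= 1 & cv$lo <= cv$p_hat & cv$p_hat <= cv$hi))

  # monotone increasing p-hat whenever the exposure coefficient is positive
  set.seed(88)
  n <- 800
  x <- rlnorm(n, 1, 0.7)
  co <- data.table::data.table(aki = runif(n) < plogis(-1.5 + 0.2 * x), twa = x)
  fit <- fit_logistic(co, model_spec("aki", "twa", character(0)))
  expect_gt(fit$coefficients["twa"], 0)
  cv <- predicted_probability_curve(fit)
  expect_true(all(diff(cv$p_hat) > 0))
  expect_warning(predicted_probability_curve(fit, grid = c(-5, 1)),
                 "outside the observed")
})

test_that("band width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(n, seed) {
    set.seed(seed)
    x <- rlnorm(n, 1, 0.7)
    co <- data.table::data.table(aki = runif(n) < plogis(-1 + 0.1 * x), twa = x)
    fit <- fit_logistic(co, model_spec("aki", "twa", character(0)))
    cv <- predicted_probability_curve(fit, grid = 2.5)
    cv$hi - cv$lo
  }
  w1 <- width_at(500, 91); w2 <- width_at(8000, 92)
  expect_lt(w2, w1 / 2)   # 16x the data -> ~4x narrower
})

test_that("analysis suite bundle has the stated structure", {
  rows <- simulate_cohort_rows(sim_config(n_patients = 1200, seed = 17))
  bundle <- run_analysis_suite(rows$cohort)
  expect_true(bundle$all_converged)
  expect_setequal(names(bundle$fits),
                  c("aki_crude", "aki_adjusted", "crrt_crude", "crrt_adjusted",
                    "aki_75", "crrt_75", "aki_htn", "aki_no_htn"))
  # subgroup fits: exactly two, neither adjusting for hypertension
  for (nm in c("aki_htn", "aki_no_htn"))
    expect_false("hypertension" %in% bundle$fits[[nm]]$spec$covariates)
  expect_equal(bundle$fits$aki_htn$n + bundle$fits$aki_no_htn$n,
               bundle$fits$aki_adjusted$n)
  # 75-mmHg sensitivity uses the recomputed exposure
  expect_equal(bundle$fits$aki_75$spec$exposure, "twa75_cpb")
  # descriptive table carries rank-sum p-values for the exposure row
  expect_true("twa65_cpb" %in% bundle$table_s1$variable)
  expect_true(all(bundle$table_s2$converged))
  # exposure effect direction recovered
  expect_gt(exposure_or(bundle$fits$aki_adjusted)$or, 1)
})
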