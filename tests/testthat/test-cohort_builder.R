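# Eligibility, attrition accounting, covariate assembly.

test_that("engineered failures land in the right attrition buckets", {
  cfg <- sim_config(n_patients = 120, seed = 21,
                    frac_no_cpb = 0.08, frac_invalid_cpb = 0.05,
                    frac_low_resolution = 0.08, p_weight_missing = 0)
  sim <- simulate_cohort(cfg)
  res <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
  att <- res$attrition
  excl <- table(sim$truth$engineered_exclusion)
  expect_equal(att$no_cpb, unname(excl["no_cpb"]))
  expect_equal(att$invalid_cpb_window, unname(excl["invalid_cpb_window"]))
  expect_equal(att$insufficient_resolution, unname(excl["insufficient_resolution"]))
  # conservation: every input operation is accounted for
  expect_equal(att$n_input,
               att$n_eligible + sum(unlist(att[setdiff(names(att),
                                                       c("n_input", "n_eligible"))])))
  # excluded patients are absent from the cohort
  bad <- sim$truth$patient_id[sim$truth$engineered_exclusion != "none"]
  expect_length(intersect(res$cohort$patient_id, bad), 0)
})

test_that("reoperations are excluded, keeping the first surgery", {
  sim <- simulate_cohort(sim_config(n_patients = 10, seed = 4, frac_no_cpb = 0,
                                    frac_invalid_cpb = 0, frac_low_resolution = 0))
  # duplicate patient 1's operation as a later reoperation
  ops2 <- data.table::copy(sim$operations)
  redo <- data.table::copy(ops2[1])
  redo[, op_id := "op_redo"]
  shift <- 5e6
  redo[, c("surgery_start", "surgery_end", "cpb_start", "cpb_stop") :=
         .(surgery_start + shift, surgery_end + shift,
           cpb_start + shift, cpb_stop + shift)]
  ops2 <- rbind(ops2, redo)
  vit2 <- rbind(sim$vitals,
                sim$vitals[op_id == ops2$op_id[1]][, .(op_id = "op_redo",
                                                       time = time + shift,
                                                       parameter, value)])
  res <- run_cohort_pipeline(vit2, ops2, sim$labs, sim$patients)
  expect_equal(res$attrition$reoperation, 1L)
  expect_true(ops2$op_id[1] %in% res$cohort$op_id)
  expect_false("op_redo" %in% res$cohort$op_id)
})

test_that("vasopressor dose aggregation follows the weight table", {
  expect_equal(vasopressor_dose_total(c("norepinephrine", "epinephrine"),
                                      c(10, 5)), 15)
  expect_equal(vasopressor_dose_total(character(0), numeric(0)), 0)
  expect_equal(vasopressor_dose_total(c("dopamine", "vasopressin"), c(100, 2)),
               100 * 0.01 + 2 * 2.5)
  expect_error(vasopressor_dose_total("drugX", 1), "drugX")
})

test_that("eGFR helper reproduces CKD-EPI 2009 reference points", {
  # independent check: hand-computed from the published equation
  # male, 60 y, SCr 0.9: 141 * 1 * (1)^-1.209 * 0.993^60 = 92.6
  expect_equal(egfr_ckdepi(0.9, 60, "m"), 141 * 0.993^60, tolerance = 1e-9)
  # female, 50 y, SCr 0.7: 141 * 1.018 * 0.993^50
  expect_equal(egfr_ckdepi(0.7, 50, "f"), 141 * 1.018 * 0.993^50,
               tolerance = 1e-9)
  # scr above kappa uses the -1.209 branch
  expect_equal(egfr_ckdepi(1.8, 60, "m"),
               141 * (1.8 / 0.9)^(-1.209) * 0.993^60, tolerance = 1e-9)
  expect_equal(as.character(egfr_stratum(c(95, 75, 50, 35, 20, 10))),
               c("G1", "G2", "G3a", "G3b", "G4", "G5"))
})

test_that("missing-covariate policies behave as stated", {
  cfg <- sim_config(n_patients = 20, seed = 6, frac_no_cpb = 0,
                    frac_invalid_cpb = 0, frac_low_resolution = 0,
                    p_weight_missing = 0)
  sim <- simulate_cohort(cfg)
  res <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
  expect_equal(nrow(res$cohort), 20)
  expect_true(all(stats::complete.cases(
    res$cohort[, intersect(model_covariates(), names(res$cohort)), with = FALSE])))

  # knock out one weight -> complete-case drops the row and logs it
  pat2 <- data.table::copy(sim$patients)
  pat2[1, weight := NA_real_]
  res2 <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, pat2)
  expect_equal(nrow(res2$cohort), 19)
  expect_equal(res2$attrition$missing_covariates, 1L)

  # impute policy keeps the row
  cfg_io <- io_config(); cfg_io$missing_policy <- "impute"
  res3 <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, pat2,
                              config = cfg_io)
  expect_equal(nrow(res3$cohort), 20)
  expect_false(anyNA(res3$cohort$weight))
})

test_that("cohort exposures satisfy threshold monotonicity row-wise", {
  sim <- simulate_cohort(sim_config(n_patients = 40, seed = 8))
  res <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
  expect_true(all(res$cohort$twa65_cpb <= res$cohort$twa75_cpb + 1e-9))
  ok <- !is.na(res$cohort$twa65_postcpb) & !is.na(res$cohort$twa75_postcpb)
  expect_true(all(res$cohort$twa65_postcpb[ok] <= res$cohort$twa75_postcpb[ok] + 1e-9))
})

test_that("every model covariate is present and non-constant in the fixture", {
  sim <- simulate_cohort(sim_config(n_patients = 200, seed = 12))
  res <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
  for (v in model_covariates()) {
    expect_true(v %in% names(res$cohort), label = paste("column", v))
    expect_gt(length(unique(res$cohort[[v]])), 1L, label = paste("variation in", v))
  }
})

test_that("cohort build is order-invariant under input shuffling", {
  sim <- simulate_cohort(sim_config(n_patients = 25, seed = 14))
  set.seed(1)
  r1 <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
  r2 <- run_cohort_pipeline(sim$vitals[sample(.N)], sim$operations[sample(.N)],
                            sim$labs[sample(.N)], sim$patients[sample(.N)])
  k1 <- r1$cohort[order(patient_id)]
  k2 <- r2$cohort[order(patient_id)]
  expect_equal(as.data.frame(k1), as.data.frame(k2), tolerance = 1e-12)
})
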