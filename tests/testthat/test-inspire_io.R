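# Readers, QC accounting, round trips.

test_that("read_vitals sorts, filters, deduplicates and counts", {
  vit <- data.table::data.table(
    op_id = "op1",
    time = c(120, 0, 60, 60, 30),
    parameter = c("art_mbp", "art_mbp", "art_mbp", "art_mbp", "hr"),
    value = c(80, 75, 70, 72, 90))
  out <- read_vitals(vit)
  s <- out$series[["op1"]]
  expect_equal(s$t, c(0, 60, 120))
  # duplicate t=60 rows (70, 72) average to 71
  expect_equal(s$value, c(75, 71, 80))
  expect_equal(out$qc$dedup_events, 1L)
  expect_equal(out$qc$rows_in, 4L)  # hr row is not MAP
  expect_equal(out$qc$rows_kept + out$qc$rows_dropped, out$qc$rows_in)

  # implausible and unparseable rows are dropped and counted
  vit2 <- data.table::data.table(
    op_id = "op1", time = c(0, 60, 120),
    parameter = "art_mbp", value = c("-5", "70", "oops"))
  out2 <- read_vitals(vit2)
  expect_equal(out2$qc$dropped_implausible, 1L)
  expect_equal(out2$qc$dropped_nonnumeric, 1L)
  expect_equal(length(out2$series[["op1"]]$t), 1L)
})

test_that("read_vitals errors on missing columns and shifts to surgery time", {
  expect_error(read_vitals(data.frame(op_id = 1, time = 1)),
               "missing required column")
  vit <- data.table::data.table(op_id = "op1", time = c(1000, 1060),
                                parameter = "art_mbp", value = c(70, 71))
  ops <- read_operations(data.table::data.table(
    op_id = "op1", patient_id = "p1", surgery_type = "cabg", emergency = FALSE,
    surgery_start = 1000, surgery_end = 5000, cpb_start = 1500, cpb_stop = 4000))
  out <- read_vitals(vit, operations = ops)
  expect_equal(out$series[["op1"]]$t, c(0, 60))
})

test_that("read_operations validates CPB windows in both dialects", {
  ops <- data.table::data.table(
    op_id = c("a", "b", "c"), patient_id = c("p1", "p2", "p3"),
    surgery_type = "cabg", emergency = FALSE,
    surgery_start = 0, surgery_end = 15000,
    cpb_start = c(3600, NA, 11000), cpb_stop = c(10800, NA, 7000))
  out <- read_operations(ops)
  expect_true(out$valid_cpb[1])
  expect_equal((out$cpb_stop[1] - out$cpb_start[1]) / 60, 120)
  expect_equal(out$reason, c(NA, "no_cpb", "invalid_cpb_window"))

  cfg <- io_config(); cfg$operations$dialect <- "events"
  ev <- data.table::data.table(op_id = c("a", "a"), time = c(3600, 10800),
                               event = c("cpb_on", "cpb_off"))
  out2 <- read_operations(ops[1, !c("cpb_start", "cpb_stop")], cfg, events = ev)
  expect_equal(out2$cpb_start, 3600)
  expect_equal(out2$cpb_stop, 10800)
  expect_error(read_operations(ops, cfg), "events table")
})

test_that("read_labs normalizes units and rejects unknown ones", {
  labs <- data.table::data.table(patient_id = "p1", time = c(10, 5),
                                 analyte = "creatinine", value = c(88.4, 106.08))
  cfg <- io_config(); cfg$labs$unit <- "umol/l"
  out <- read_labs(labs, cfg)
  expect_equal(out$labs$value, c(1.2, 1.0))  # sorted by time
  mg <- data.table::data.table(patient_id = "p1", time = c(5, 10),
                               analyte = "creatinine", value = c(1.2, 0.9))
  expect_equal(read_labs(mg)$labs$value, c(1.2, 0.9))  # mg/dL passthrough
  cfg$labs$unit <- "furlongs"
  expect_error(read_labs(labs, cfg), "unknown creatinine unit")
  # empty series after filtering
  none <- read_labs(labs[analyte == "glucose"])
  expect_equal(nrow(none$labs), 0L)
})

test_that("reader output is invariant to input row order", {
  set.seed(5)
  vit <- data.table::data.table(
    op_id = sample(c("a", "b"), 200, TRUE),
    time = sample(seq(0, 6000, 30), 200, TRUE),
    parameter = "art_mbp", value = round(runif(200, 40, 100), 1))
  o1 <- read_vitals(vit)
  o2 <- read_vitals(vit[sample(.N)])
  expect_identical(o1$series[["a"]]$t, o2$series[["a"]]$t)
  expect_identical(o1$series[["a"]]$value, o2$series[["a"]]$value)
  expect_identical(o1$qc, o2$qc)
})

test_that("cohort CSV round trip preserves values", {
  rows <- simulate_cohort_rows(sim_config(n_patients = 30, seed = 3))$cohort
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rows, p)
  back <- read_cohort(p)
  expect_equal(back$patient_id, rows$patient_id)
  expect_equal(back$aki, rows$aki)
  for (v in c("twa65_cpb", "twa75_cpb", "cpb_time", "euroscore2"))
    expect_equal(back[[v]], rows[[v]], tolerance = 1e-12)
})

test_that("yaml config merges over defaults recursively", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("max_gap_min: 3", "labs:", "  unit: umol/l"), p)
  cfg <- load_config(p)
  expect_equal(cfg$max_gap_min, 3)
  expect_equal(cfg$labs$unit, "umol/l")
  expect_equal(cfg$labs$creatinine, "creatinine")  # untouched default
})

test_that("csv files read identically to in-memory tables", {
  sim <- simulate_cohort(sim_config(n_patients = 15, seed = 9))
  paths <- write_tiny_tables(sim$vitals, sim$operations, sim$labs, sim$patients)
  r1 <- run_cohort_pipeline(sim$vitals, sim$operations, sim$labs, sim$patients)
  r2 <- run_cohort_pipeline(paths$vitals, paths$operations, paths$labs,
                            paths$patients)
  expect_equal(as.data.frame(r1$cohort), as.data.frame(r2$cohort),
               tolerance = 1e-9)
  expect_identical(r1$attrition, r2$attrition)
})
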