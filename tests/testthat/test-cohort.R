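test_that("the packaged case cohort reads with observations and indicators", {
  path <- system.file("extdata", "case_cohort.csv", package = "motcast")
  co <- read_cohort(path)
  expect_s3_class(co, "cohort")
  expect_identical(patient_ids(co), "Jstar")
  traj <- patient_trajectory(co, "Jstar")
  expect_equal(nrow(traj$observations), 7L)
  expect_equal(traj$observations$age_months, seq(15, 105, by = 15))
  expect_equal(traj$observations$value,
               c(3.00, 7.00, 13.25, 13.25, 15.50, 19.25, 25.00))
  expect_equal(traj$risk_indicators, c(P1 = 0, P2 = 1, P3 = 1))
})

test_that("malformed cohort CSVs are rejected with informative errors", {
  write_csv <- function(lines) {
    f <- tmp_path(".csv")
    writeLines(lines, f)
    f
  }
  expect_error(read_cohort(write_csv("patient_id,age_months,value")),
               "no observations")
  expect_error(
    read_cohort(write_csv(c("patient_id,age_months,value",
                            "a,10,5", "a,10,6"))),
    "duplicate \\(patient, age\\) pair \\(a, 10\\) on line 3")
  expect_error(
    read_cohort(write_csv(c("patient_id,age_months,value",
                            "a,10,75"))),
    "outside index bounds .* line\\(s\\) 2")
  expect_error(
    read_cohort(write_csv(c("patient_id,age_months,value,P1",
                            "a,10,5,2"))),
    "non-binary entry in factor column 'P1' on line\\(s\\) 2")
  expect_error(
    read_cohort(write_csv(c("patient_id,age_months,value,P1",
                            "a,10,5,1", "a,20,6,0"))),
    "factor indicators vary within patient a")
})

test_that("cohort CSV round-trip preserves every tuple exactly", {
  sim <- generate_cohort(generator_config(n_patients = 8, seed = 5))
  f <- tmp_path(".csv")
  write_cohort(sim$cohort, f)
  back <- read_cohort(f)
  expect_equal(back$observations, sim$cohort$observations)
  expect_equal(back$factors, sim$cohort$factors)
  expect_identical(back$factor_names, sim$cohort$factor_names)
})

test_that("cohort() validates bounds, duplicates and binary factors", {
  obs <- data.frame(patient_id = "a", age_months = c(1, 2), value = c(5, 6))
  expect_s3_class(cohort(obs), "cohort")
  expect_error(cohort(obs[0, ]), "no observations")
  expect_error(cohort(data.frame(patient_id = "a", age_months = -1, value = 5)),
               "non-negative")
  expect_error(cohort(data.frame(patient_id = "a", age_months = 1, value = 61)),
               "outside index bounds")
  expect_error(
    cohort(data.frame(patient_id = "a", age_months = c(3, 3), value = c(1, 2))),
    "duplicate \\(patient, age\\) pair: \\(a, 3\\)")
  expect_error(
    cohort(obs, factors = data.frame(patient_id = "a", P1 = 0.5)),
    "must be binary")
  expect_error(
    cohort(obs, factors = data.frame(patient_id = "zz", P1 = 1)),
    "unknown patient")
})

test_that("split_trajectory partitions the case trajectory as published", {
  co <- worked_example_cohort()
  traj <- patient_trajectory(co, "Jstar")
  sp <- split_trajectory(traj, base_end_age = 48, horizon_age = 105)
  expect_equal(sp$base$age_months, c(15, 30, 45))
  expect_equal(sp$control$age_months, c(60, 75, 90, 105))
  # exhaustive partition up to the horizon
  expect_equal(sort(c(sp$base$age_months, sp$control$age_months)),
               traj$observations$age_months)
})

test_that("split_trajectory boundary and error cases behave", {
  co <- worked_example_cohort()
  traj <- patient_trajectory(co, "Jstar")
  # base end at the very first age keeps only that observation
  sp <- split_trajectory(traj, 15, 105)
  expect_equal(sp$base$age_months, 15)
  expect_equal(sp$base$value, 3.00)
  # base end beyond the last age puts everything in base
  sp2 <- split_trajectory(traj, 200, 300)
  expect_equal(nrow(sp2$base), 7L)
  expect_equal(nrow(sp2$control), 0L)
  # observations past the horizon are dropped unless asked for
  sp3 <- split_trajectory(traj, 48, 90)
  expect_equal(sp3$control$age_months, c(60, 75, 90))
  sp4 <- split_trajectory(traj, 48, 90, include_beyond_horizon = TRUE)
  expect_equal(sp4$control$age_months, c(60, 75, 90, 105))
  # no base observations is an error
  expect_error(split_trajectory(traj, 10, 105), "no base-period observations")
  expect_error(split_trajectory(traj, 50, 40), "base_end_age < horizon_age")
})
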