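test_that("the published intercept adjustment is reproduced arithmetically", {
  ex <- worked_example()
  co <- worked_example_cohort()
  sp <- split_trajectory(patient_trajectory(co, "Jstar"),
                         ex$split$base_end_age, ex$split$horizon_age)
  phi <- compute_phi(ex$weights, ex$indicators)
  fit <- fit_individual(sp$base, ex$trend$rates, ex$split$horizon_age,
                        y_max = ex$y_max, phi = phi, mu = ex$constants$mu,
                        intercept_no_risk = ex$constants$intercept_no_risk)
  expect_equal(fit$adjusted_intercept, -14.1756)
  # the published value -14.17 is the two-decimal truncation of -14.1756
  expect_equal(trunc(fit$adjusted_intercept * 100) / 100, -14.17)
  expect_null(fit$stage1)
  expect_true(all(fit$model$amplitudes >= 0))
  expect_true(fit$model$monotone)
})

test_that("with no risk factors stage 2 refits amplitudes at the stage-1
           intercept", {
  set.seed(71)
  sched <- c(6, 12, 24, 36, 48)
  truth <- exp_trend(-5, c(30, 15), c(0.02, 0.1), monotone = TRUE)
  base <- data.frame(age_months = sched,
                     value = predict(truth, sched) + rnorm(5, 0, 1))
  fit <- fit_individual(base, truth$rates, 105, y_max = 60, phi = 0, mu = -16)
  expect_equal(fit$adjusted_intercept, fit$intercept_no_risk)
  # re-solving with the intercept fixed at the stage-1 optimum keeps the
  # stage-1 amplitudes
  expect_equal(unname(fit$stage2$coefficients),
               unname(fit$stage1$coefficients[-1]), tolerance = 1e-6)
})

test_that("fixing the intercept away from the stage-1 optimum cannot
           improve the fit", {
  set.seed(72)
  for (i in 1:20) {
    sched <- sort(sample(seq(3, 48, by = 3), 5))
    truth <- random_monotone_model()
    base <- data.frame(age_months = sched,
                       value = pmin(pmax(
                         predict(truth, sched) + rnorm(5, 0, 2), -100), 100))
    phi <- runif(1, 0, 1.2)
    fit <- fit_individual(base, c(0.02, 0.1), 105, y_max = 100,
                          phi = phi, mu = -16.68)
    expect_gte(fit$stage2$objective, fit$stage1$objective - 1e-8)
    # the fitted model respects the ceiling at the horizon
    expect_lte(predict(fit$model, 105), 100 + 1e-8)
  }
})

test_that("the fitted model stays at or below the ceiling at the horizon", {
  set.seed(73)
  for (i in 1:30) {
    sched <- sort(sample(seq(3, 60, by = 3), sample(3:8, 1)))
    vals <- sort(runif(length(sched), 0, 60))
    base <- data.frame(age_months = sched, value = vals)
    fit <- fit_individual(base, c(0.015, 0.12), 108, y_max = 60,
                          phi = runif(1, 0, 1), mu = runif(1, -20, 0))
    expect_lte(predict(fit$model, 108), 60 + 1e-8)
  }
})

test_that("predictions evaluate the individual model pointwise", {
  m <- exp_trend(-14.17, c(60.52, 17.04), c(0.01, 0.09), monotone = TRUE)
  expect_equal(predict(m, 0), -14.17)
  v <- predict(m, 0:120)
  expect_true(all(diff(v) >= 0))
  expect_error(predict(m, c(5, -5)), "non-negative")
})

test_that("an individual generated from a known model is recovered on the
           control period when noise vanishes", {
  # no-risk patient: stage 1 alone identifies the generative intercept
  cfg0 <- generator_config(n_patients = 1, noise_sd = 0,
                           intercept_noise_sd = 0, amplitude_spread = 0,
                           factor_model = data.frame(
                             name = "P1", prevalence = 0, delta = -0.5),
                           seed = 74)
  sim0 <- generate_cohort(cfg0)
  id <- patient_ids(sim0$cohort)
  sp <- split_trajectory(patient_trajectory(sim0$cohort, id), 48, 105)
  fit0 <- fit_individual(sp$base, cfg0$true_trend$rates, 105, y_max = 60,
                         phi = 0, mu = cfg0$mu_true)
  expect_equal(predict(fit0$model, sp$control$age_months),
               sp$control$value, tolerance = 1e-4)

  # at-risk patient: with the no-risk intercept known, the mu-phi
  # adjustment lands on the generative intercept and stage 2 recovers
  # the curve
  cfg1 <- generator_config(n_patients = 6, noise_sd = 0,
                           intercept_noise_sd = 0, amplitude_spread = 0,
                           seed = 75)
  sim1 <- generate_cohort(cfg1)
  at_risk <- Filter(function(id) sim1$truth[[id]]$phi > 0,
                    patient_ids(sim1$cohort))
  expect_gt(length(at_risk), 0)
  id <- at_risk[[1]]
  truth <- sim1$truth[[id]]
  sp <- split_trajectory(patient_trajectory(sim1$cohort, id), 48, 105)
  fit1 <- fit_individual(sp$base, cfg1$true_trend$rates, 105, y_max = 60,
                         phi = truth$phi, mu = cfg1$mu_true,
                         intercept_no_risk = cfg1$base_intercept)
  expect_equal(fit1$adjusted_intercept, truth$intercept)
  expect_equal(predict(fit1$model, sp$control$age_months),
               sp$control$value, tolerance = 1e-4)
})
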