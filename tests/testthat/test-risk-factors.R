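test_that("the generalized factor of the case patient is 0.67", {
  ex <- worked_example()
  phi <- compute_phi(ex$weights, ex$indicators)
  expect_equal(phi$phi, 0.67)
  expect_equal(phi$signed_sum, -0.67)
  expect_equal(unname(phi$contributions), c(0, -0.39, -0.28))
})

test_that("compute_phi conventions, degenerate inputs and errors", {
  w <- factor_weights(c("P1", "P2", "P3"), c(-0.50, -0.39, -0.28))
  # no risk factors present
  expect_equal(compute_phi(w, c(P1 = 0, P2 = 0, P3 = 0))$phi, 0)
  # signed convention keeps the sign
  w1 <- factor_weights("F", -0.5)
  p_signed <- compute_phi(w1, c(F = 1), convention = "signed")
  expect_equal(p_signed$phi, -0.5)
  expect_equal(p_signed$signed_sum, -0.5)
  # missing indicator is named
  expect_error(compute_phi(w, c(P1 = 1, P2 = 0)), "P3")
  expect_error(compute_phi(w1, c(F = 2)), "binary")
})

test_that("signed phi is additive over disjoint indicator sets and
           magnitude phi is invariant to a global sign flip", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    nm <- paste0("F", seq_len(k))
    d <- runif(k, -1, 1)
    w <- factor_weights(nm, d, selection_threshold = 0)
    p <- rbinom(k, 1, 0.5)
    q <- ifelse(p == 1, 0, rbinom(k, 1, 0.5))  # disjoint support
    s <- function(ind) compute_phi(w, setNames(ind, nm),
                                   convention = "signed")$phi
    expect_equal(s(p + q), s(p) + s(q))
    w_flipped <- factor_weights(nm, -d, selection_threshold = 0)
    expect_equal(compute_phi(w, setNames(p, nm))$phi,
                 compute_phi(w_flipped, setNames(p, nm))$phi)
  }
})

test_that("factor correlations recover association strength and screening", {
  # a factor exactly equal to (initial value below median) correlates
  # perfectly with the initial value of a two-point cohort
  obs <- data.frame(patient_id = rep(paste0("p", 1:6), each = 1),
                    age_months = 1,
                    value = c(5, 5, 5, 45, 45, 45))
  fac <- data.frame(patient_id = paste0("p", 1:6),
                    LOW = c(1, 1, 1, 0, 0, 0))
  co <- cohort(obs, factors = fac)
  fw <- factor_correlations(co)
  expect_equal(abs(fw$entries$delta), 1, tolerance = 1e-10)
  expect_lt(fw$entries$delta, 0)  # indicator coded against high values

  # an independent factor on many patients screens out
  set.seed(41)
  n <- 500
  obs2 <- data.frame(patient_id = sprintf("q%03d", 1:n), age_months = 1,
                     value = runif(n, 0, 60))
  fac2 <- data.frame(patient_id = sprintf("q%03d", 1:n),
                     NOISE = rbinom(n, 1, 0.5))
  co2 <- cohort(obs2, factors = fac2)
  fw2 <- factor_correlations(co2, selection_threshold = 0)
  expect_lt(abs(fw2$entries$delta), 0.15)
  # and falls below the default retention threshold
  expect_equal(nrow(factor_correlations(co2)$entries), 0L)

  # constant factors are dropped with a warning
  fac3 <- cbind(fac2, CONST = 1)
  co3 <- cohort(obs2, factors = fac3)
  expect_warning(fw3 <- factor_correlations(co3, selection_threshold = 0),
                 "CONST")
  expect_identical(fw3$entries$factor, "NOISE")
})

test_that("published-style weights survive the default threshold", {
  fw <- factor_weights(c("P1", "P2", "P3"), c(-0.50, -0.39, -0.28),
                       selection_threshold = 0.25)
  expect_equal(nrow(fw$entries), 3L)
  expect_equal(fw$entries$delta, c(-0.50, -0.39, -0.28))  # |delta| descending
  f <- tmp_path(".json")
  write_weights(fw, f)
  expect_equal(read_weights(f), fw, ignore_attr = TRUE)
})

test_that("estimate_mu is exact on collinear data and errors when
           unidentifiable", {
  mk <- function(values, phis_ind) {
    n <- length(values)
    obs <- data.frame(patient_id = paste0("p", 1:n), age_months = 1,
                      value = values)
    fac <- data.frame(patient_id = paste0("p", 1:n), A = phis_ind[, 1],
                      B = phis_ind[, 2])
    cohort(obs, factors = fac)
  }
  # weights (-0.5, -0.5) give phi in {0, 0.5, 1}; y = 10 - 10 * phi
  w <- factor_weights(c("A", "B"), c(-0.5, -0.5))
  co <- mk(c(10, 5, 0), cbind(c(0, 1, 1), c(0, 0, 1)))
  mu <- estimate_mu(co, w)
  expect_equal(as.numeric(mu), -10)
  expect_equal(attr(mu, "n"), 3L)
  # identical initial values -> zero slope
  co2 <- mk(c(7, 7, 7), cbind(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(as.numeric(estimate_mu(co2, w)), 0)
  # constant phi -> unidentifiable
  co3 <- mk(c(1, 2, 3), cbind(c(1, 1, 1), c(0, 0, 0)))
  expect_error(estimate_mu(co3, w), "unidentifiable")
})

test_that("estimate_mu recovers a noise-free linear intercept model exactly", {
  set.seed(55)
  sim <- generate_cohort(generator_config(
    n_patients = 40, noise_sd = 0, intercept_noise_sd = 0,
    amplitude_spread = 0, seed = 55))
  w <- factor_weights(c("P1", "P2", "P3"), c(-0.50, -0.39, -0.28))
  mu <- estimate_mu(sim$cohort, w)
  # the initial value is the model at 15 months: intercept + constant,
  # so the slope on phi is exactly mu_true
  expect_equal(as.numeric(mu), -16.68, tolerance = 1e-8)
})
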