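test_that("build_problem assembles the design, targets and ceiling exactly", {
  base <- data.frame(age_months = c(15, 30, 45),
                     value = c(3.00, 7.00, 13.25))
  prob <- build_problem(base, rates = c(0.01, 0.09), t_horizon = 105,
                        y_max = 60)
  expect_equal(dim(prob$design), c(3L, 3L))
  expect_equal(prob$design[, 1], rep(1, 3))
  expect_equal(unname(prob$design[1, 3]), 1 - exp(-1.35))
  expect_equal(unname(prob$design[3, 2]), 1 - exp(-0.45))
  expect_equal(prob$ceiling, c(1, 1 - exp(-0.01 * 105), 1 - exp(-0.09 * 105)))
  expect_equal(prob$y_max, 60)
  # an observation at age 0 contributes only to the intercept column
  prob0 <- build_problem(data.frame(age_months = 0, value = 2), 0.05, 100)
  expect_equal(unname(prob0$design[1, ]), c(1, 0))
  # fixing the intercept shifts targets and the ceiling right-hand side
  probf <- build_problem(base, c(0.01, 0.09), 105, y_max = 60,
                         fixed_intercept = -14.17)
  expect_equal(ncol(probf$design), 2L)
  expect_equal(probf$targets, base$value + 14.17)
  expect_equal(probf$y_max, 74.17)
})

test_that("clamping a sign-constrained regressor to zero is optimal", {
  # y is strictly decreasing in x, so the best non-negative slope is 0
  # and the objective is sum(y^2) = 14
  prob <- cfit_problem(matrix(c(1, 2, 3)), c(-1, -2, -3), nonneg = 1L)
  fit <- solve_active_set(prob)
  expect_equal(unname(fit$coefficients), 0)
  expect_equal(fit$objective, 14)
  expect_identical(fit$active_set, "nonneg:A0")
  expect_gt(fit$multipliers[["nonneg:A0"]], 0)
})

test_that("inactive constraints reproduce ordinary least squares", {
  set.seed(61)
  tg <- c(6, 18, 36, 54, 72)
  X <- cbind(1, 1 - exp(-0.05 * tg))
  y <- 2 + 20 * X[, 2] + rnorm(5, 0, 0.5)
  prob <- cfit_problem(X, y, nonneg = 2L, ceiling = c(1, 1 - exp(-0.05 * 120)),
                       y_max = 60)
  fit <- solve_active_set(prob)
  ols <- unname(qr.coef(qr(X), y))
  expect_equal(unname(fit$coefficients), ols, tolerance = 1e-9)
  expect_length(fit$active_set, 0L)
  expect_equal(solve_oracle(prob)$objective, fit$objective, tolerance = 1e-12)
})

test_that("a two-variable fit with one violated bound activates it with a
           positive multiplier", {
  # unconstrained solution has a negative second coefficient
  X <- cbind(c(1, 1, 1, 1), c(0, 1, 2, 3))
  y <- c(10, 9, 8, 7)
  prob <- cfit_problem(X, y, nonneg = 2L)
  fit <- solve_active_set(prob)
  expect_identical(fit$active_set, "nonneg:A1")
  expect_equal(unname(fit$coefficients), c(mean(y), 0))
  expect_gt(fit$multipliers[["nonneg:A1"]], 0)
  oracle <- solve_oracle(prob)
  expect_equal(oracle$objective, fit$objective, tolerance = 1e-12)
  expect_identical(oracle$active_set, fit$active_set)
})

test_that("a ceiling below the unconstrained horizon value becomes active", {
  tg <- c(10, 20, 30)
  rates <- 0.05
  base <- data.frame(age_months = tg, value = c(20, 32, 40))
  prob <- build_problem(base, rates, t_horizon = 120, y_max = 45)
  unconstrained <- qr.coef(qr(prob$design), prob$targets)
  horizon_value <- sum(unconstrained * prob$ceiling)
  expect_gt(horizon_value, 45)            # the instance is genuinely binding
  fit <- solve_active_set(prob)
  expect_true("ceiling" %in% fit$active_set)
  expect_lte(sum(fit$coefficients * prob$ceiling), 45 + 1e-8)
  expect_equal(solve_oracle(prob)$objective, fit$objective,
               tolerance = 1e-12)
})

test_that("the active-set solver matches the exhaustive oracle on random
           problems", {
  set.seed(4242)
  for (k in 1:400) {
    prob <- random_cfit_problem()
    a <- solve_active_set(prob)
    b <- solve_oracle(prob)
    expect_lt(abs(a$objective - b$objective) / max(1, b$objective), 1e-10)
    expect_lt(max(abs(a$coefficients - b$coefficients)), 1e-8)
    # complementary slackness and dual feasibility at the solution
    expect_true(all(a$multipliers >= -1e-9))
    expect_lt(a$kkt_residual, 1e-6)
  }
})

test_that("rank-deficient problems are solved deterministically and flagged", {
  # 2 observations, 3 parameters: the boundary case of an early base period
  base <- data.frame(age_months = c(15, 30), value = c(3, 7))
  prob <- build_problem(base, c(0.01, 0.09), 105, y_max = 60)
  expect_false(prob$full_rank)
  fit <- solve_active_set(prob)
  expect_true(fit$non_unique)
  expect_equal(fit$objective, solve_oracle(prob)$objective, tolerance = 1e-10)
  expect_identical(fit$coefficients, solve_active_set(prob)$coefficients)
})

test_that("infeasible and oversized problems error out", {
  # fixed intercept above the ceiling leaves no feasible amplitudes
  base <- data.frame(age_months = c(15, 30, 45), value = c(3, 7, 13))
  prob <- build_problem(base, 0.05, 105, y_max = 60, fixed_intercept = 80)
  expect_error(solve_active_set(prob), "infeasible")
  big <- cfit_problem(matrix(rnorm(15 * 13), 15, 13), rnorm(15),
                      nonneg = 1:13)
  expect_error(solve_oracle(big), "solve_active_set")
})
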