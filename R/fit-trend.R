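#' Logarithmic decay-rate grid
#'
#' @param min,max grid endpoints (per month), both positive.
#' @param points number of grid points.
#' @return Numeric vector of `points` log-spaced rates.
#' @export
rate_grid <- function(min = 1e-4, max = 1, points = 200L) {
  stopifnot(min > 0, max > min, points >= 2L)
  exp(seq(log(min), log(max), length.out = points))
}

# Refit all linear coefficients (intercept + amplitudes) for fixed rates.
# Non-negative amplitudes when monotone; returns NULL on failure.
refit_linear <- function(tg, y, rates, monotone) {
  growth <- if (length(rates)) 1 - exp(-outer(tg, rates)) else
    matrix(0, length(tg), 0)
  design <- cbind(1, growth)
  colnames(design) <- c("a0", if (length(rates)) paste0("a", seq_along(rates)))
  if (monotone && length(rates)) {
    prob <- cfit_problem(design, y, nonneg = seq_along(rates) + 1L)
    fit <- tryCatch(solve_active_set(prob), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    coef <- unname(fit$coefficients)
    ssr <- fit$objective
  } else {
    coef <- tryCatch(unname(qr.coef(qr(design), y)), error = function(e) NULL)
    if (is.null(coef) || anyNA(coef)) return(NULL)
    ssr <- sum((y - drop(design %*% coef))^2)
  }
  list(coef = coef, ssr = ssr)
}

#' Identify the cohort-average trend
#'
#' Greedy "consecutive selection of exponential terms": starting from the
#' pooled-mean constant model, each stage scans a logarithmic grid of
#' candidate decay rates, refits *all* linear coefficients (intercept and
#' amplitudes; non-negative amplitudes when `monotone`) for each
#' candidate, keeps the rate that maximizes the pooled R-squared, refines
#' it by one-dimensional optimization in log-rate, and accepts the term
#' only if it captures at least `stop_tol` of the remaining unexplained
#' variance. After each accepted term the accepted rates are polished by
#' deterministic backfitting sweeps (each rate re-optimized in turn,
#' until the fit stops improving). All observations of all patients
#' are pooled, unweighted. The procedure involves no randomness:
#' refitting the same cohort yields the identical model.
#'
#' @param cohort a [cohort()] object.
#' @param max_terms maximum number of exponential terms Q (default 3).
#' @param grid candidate decay rates, e.g. [rate_grid()] (default 200
#'   log-spaced points in `[1e-4, 1]` per month).
#' @param stop_tol minimum relative R-squared gain
#'   `(R2_new - R2_old) / (1 - R2_old)` to accept a term (default 0.01).
#' @param monotone constrain amplitudes non-negative (default `TRUE`).
#' @param refine refine each accepted rate by [stats::optimize()] around
#'   its best grid point and backfit (default `TRUE`).
#' @param min_rate_ratio reject candidate rates within this factor of an
#'   already-accepted rate (default 1.05), avoiding a near-singular
#'   design.
#' @return An [exp_trend()] model with a `diagnostics` attribute: pooled
#'   `r_squared`, `n_obs`, per-stage gains, and any early-stop warnings.
#' @export
fit_average_trend <- function(cohort, max_terms = 3L, grid = rate_grid(),
                              stop_tol = 0.01, monotone = TRUE,
                              refine = TRUE, min_rate_ratio = 1.05) {
  stopifnot(inherits(cohort, "cohort"))
  tg <- cohort$observations$age_months
  y <- cohort$observations$value
  n <- length(y)
  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2)
  diagnostics <- list(n_obs = n, stages = list(), warnings = character())
  BIG_SSR <- sum(y^2) + ss_tot + 1   # finite penalty for invalid candidates

  wrap <- function(coef, rates, r2) {
    m <- exp_trend(coef[1L], if (length(rates)) coef[-1L] else numeric(),
                   rates, monotone = monotone,
                   bounds = c(cohort$value_min, cohort$value_max))
    diagnostics$r_squared <- r2
    attr(m, "diagnostics") <- diagnostics
    m
  }

  if (ss_tot <= 1e-12 * max(1, ybar^2) * n)   # constant data
    return(wrap(ybar, numeric(0), NA_real_))
  r2_of <- function(ssr) 1 - ssr / ss_tot

  rates <- numeric(0)
  coef <- ybar
  r2 <- 0
  for (q in seq_len(max_terms)) {
    if (n < 2L * q + 1L) {
      diagnostics$warnings <- c(diagnostics$warnings, sprintf(
        "stopped before term %d: %d observations < %d parameters", q, n,
        2L * q + 1L))
      warning(diagnostics$warnings[length(diagnostics$warnings)])
      break
    }
    ok <- vapply(grid, function(l)
      !length(rates) || all(pmax(l, rates) / pmin(l, rates) >= min_rate_ratio),
      TRUE)
    cand <- grid[ok]
    if (!length(cand)) break
    ssr_cand <- vapply(cand, function(l) {
      f <- refit_linear(tg, y, c(rates, l), monotone)
      if (is.null(f)) Inf else f$ssr
    }, 0)
    if (!any(is.finite(ssr_cand))) break
    best_i <- which.min(ssr_cand)
    best_rate <- cand[best_i]

    if (refine) {
      lo <- if (best_i > 1L) cand[best_i - 1L] else cand[1L]
      hi <- if (best_i < length(cand)) cand[best_i + 1L] else cand[length(cand)]
      if (hi > lo) {
        opt <- stats::optimize(function(ll) {
          f <- refit_linear(tg, y, c(rates, exp(ll)), monotone)
          if (is.null(f)) BIG_SSR else f$ssr
        }, interval = log(c(lo, hi)), tol = 1e-8)
        refined <- exp(opt$minimum)
        dup <- length(rates) &&
          any(pmax(refined, rates) / pmin(refined, rates) < min_rate_ratio)
        if (!dup && opt$objective <= ssr_cand[best_i]) best_rate <- refined
      }
    }

    fit <- refit_linear(tg, y, c(rates, best_rate), monotone)
    if (is.null(fit)) break
    r2_new <- r2_of(fit$ssr)
    gain <- (r2_new - r2) / max(1 - r2, 1e-12)
    if (gain < stop_tol) break
    rates <- c(rates, best_rate)
    coef <- fit$coef
    r2 <- r2_new

    if (refine && length(rates)) {        # backfitting sweeps over accepted rates
      cur <- fit
      for (sweep in 1:25) {
        ssr_before <- cur$ssr
        for (j in seq_along(rates)) {
          others <- rates[-j]
          opt <- stats::optimize(function(ll) {
            l <- exp(ll)
            if (length(others) &&
                any(pmax(l, others) / pmin(l, others) < min_rate_ratio))
              return(BIG_SSR)
            f <- refit_linear(tg, y, append(others, l, after = j - 1L),
                              monotone)
            if (is.null(f)) BIG_SSR else f$ssr
          }, interval = log(range(grid)), tol = 1e-8)
          cand_rates <- append(others, exp(opt$minimum), after = j - 1L)
          f <- refit_linear(tg, y, cand_rates, monotone)
          if (!is.null(f) && f$ssr <= cur$ssr + 1e-12) {
            rates <- cand_rates
            cur <- f
          }
        }
        if (ssr_before - cur$ssr <= 1e-10 * max(ssr_before, 1e-12)) break
      }
      coef <- cur$coef
      r2 <- r2_of(cur$ssr)
    }
    diagnostics$stages[[q]] <- list(rate = rates[length(rates)],
                                    r_squared = r2, gain = gain)
  }
  wrap(coef, rates, r2)
}
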