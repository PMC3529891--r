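#' Two-stage identification of an individual trend model
#'
#' Stage 1 fits the individual model to the base-period observations
#' with a *free* intercept, yielding the patient's index at the initial
#' time with no risk factors accounted for, \eqn{A_0|_{\Phi=0}}. The
#' intercept is then adjusted for the patient's perinatal/intranatal
#' risk, \eqn{A_0 = A_0|_{\Phi=0} + \mu\Phi}. Stage 2 re-solves the same
#' constrained least-squares problem with the intercept *fixed* at the
#' adjusted value, yielding the non-negative amplitudes \eqn{A_q}. Both
#' stages enforce monotone growth (amplitudes at or above zero) and the
#' index ceiling at the prediction horizon, and are solved exactly by
#' [solve_active_set()].
#'
#' @param base_obs base-period observations (data frame `age_months`,
#'   `value`), e.g. `split_trajectory(...)$base`.
#' @param rates cohort decay rates \eqn{\lambda_q} from
#'   [fit_average_trend()].
#' @param t_horizon prediction horizon (months).
#' @param y_max highest possible index value (default 60).
#' @param phi the patient's generalized factor: a [compute_phi()] result
#'   or a plain scalar.
#' @param mu intercept-adjustment slope from [estimate_mu()].
#' @param intercept_no_risk optional externally supplied
#'   \eqn{A_0|_{\Phi=0}}; when given, stage 1 is skipped and this value
#'   is adjusted directly (useful to reproduce analyses whose stage-1
#'   value was published but whose inputs were not).
#' @param tol solver tolerance, see [solve_active_set()].
#' @return An object of class `"individual_fit"`: `stage1` (a
#'   `cfit_result`, or `NULL` if skipped), `intercept_no_risk`,
#'   `adjusted_intercept`, `stage2` (a `cfit_result`), and `model` (the
#'   final monotone [exp_trend()]).
#' @export
fit_individual <- function(base_obs, rates, t_horizon, y_max = 60,
                           phi = 0, mu = 0, intercept_no_risk = NULL,
                           tol = 1e-9) {
  phi_val <- if (inherits(phi, "phi_result")) phi$phi else as.numeric(phi)
  stopifnot(is.numeric(mu), length(mu) == 1L)

  stage1 <- NULL
  if (is.null(intercept_no_risk)) {
    p1 <- build_problem(base_obs, rates, t_horizon, y_max = y_max)
    stage1 <- solve_active_set(p1, tol = tol)
    intercept_no_risk <- unname(stage1$coefficients[1L])
  }
  adjusted <- intercept_no_risk + mu * phi_val

  p2 <- build_problem(base_obs, rates, t_horizon, y_max = y_max,
                      fixed_intercept = adjusted)
  stage2 <- solve_active_set(p2, tol = tol)
  amps <- pmax(unname(stage2$coefficients), 0)   # exact zeros at the bound
  model <- exp_trend(adjusted, amps, rates, monotone = TRUE,
                     bounds = c(-Inf, y_max))
  structure(
    list(stage1 = stage1, intercept_no_risk = intercept_no_risk,
         adjusted_intercept = adjusted, phi = phi_val, mu = mu,
         stage2 = stage2, model = model),
    class = "individual_fit"
  )
}

#' @export
print.individual_fit <- function(x, ...) {
  cat(sprintf("<individual_fit> A0|Phi=0 = %.4f%s, phi = %g, mu = %g\n",
              x$intercept_no_risk,
              if (is.null(x$stage1)) " (supplied)" else "", x$phi, x$mu))
  cat(sprintf("  adjusted intercept A0 = %.4f\n", x$adjusted_intercept))
  print(x$model)
  invisible(x)
}
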