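#' Prediction-quality metrics
#'
#' Determination coefficient and root-mean-square error of predictions
#' against observations:
#' \deqn{R^2 = 1 - SS_{res}/SS_{tot},} with \eqn{SS_{tot}} taken about
#' the observations' own mean. When the observations are all identical
#' (\eqn{SS_{tot} = 0}) the determination coefficient is undefined and
#' reported as `NA`; the RMSE is still computed.
#'
#' @param observed,predicted numeric vectors of equal positive length.
#' @param ages optional ages for the per-point table.
#' @return An object of class `"evaluation_report"`: `r_squared`,
#'   `rmse`, `n_control`, and a `per_point` data frame with columns
#'   `age`, `observed`, `predicted`, `residual`.
#' @export
prediction_metrics <- function(observed, predicted, ages = NULL) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) == 0L || length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal positive length")
  if (is.null(ages)) ages <- rep(NA_real_, length(observed))
  resid <- observed - predicted
  ss_res <- sum(resid^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(r_squared = r2, rmse = sqrt(mean(resid^2)),
         n_control = length(observed),
         per_point = data.frame(age = ages, observed = observed,
                                predicted = predicted, residual = resid)),
    class = "evaluation_report"
  )
}

#' Evaluate a model against held-out observations
#'
#' Evaluates the individual (or average) trend model at the control
#' observations' ages and summarizes prediction quality with
#' [prediction_metrics()]. By convention the control period is the
#' held-out later window of [split_trajectory()], so the reported
#' \eqn{R^2} measures genuine out-of-window prediction.
#'
#' @param model an [exp_trend()] model.
#' @param control data frame of held-out observations (`age_months`,
#'   `value`); must be non-empty.
#' @return An `"evaluation_report"`, see [prediction_metrics()].
#' @export
evaluate_prediction <- function(model, control) {
  stopifnot(inherits(model, "exp_trend"))
  if (!is.data.frame(control) ||
      !all(c("age_months", "value") %in% names(control)))
    stop("`control` must have columns age_months and value")
  if (nrow(control) == 0L)
    stop("control period is empty")
  prediction_metrics(control$value, predict(model, control$age_months),
                     ages = control$age_months)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, R^2 = %s, RMSE = %.4g\n",
              x$n_control,
              if (is.na(x$r_squared)) "undefined" else
                sprintf("%.4f", x$r_squared),
              x$rmse))
  invisible(x)
}
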