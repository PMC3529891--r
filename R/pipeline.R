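#' Run the full individual-prediction workflow
#'
#' Executes, in order: average-trend identification (or an override),
#' the between-age correlation diagnostic, risk-factor selection (or an
#' override), estimation of the adjustment slope \eqn{\mu} (or an
#' override), the two-stage constrained fit per patient, and evaluation
#' on the held-out control period. Every intermediate artifact is
#' written under `output_dir` (`trend.json`, `surface.csv`,
#' `weights.json`, `models/<patient>.json`, `report.json`); re-running
#' with identical inputs reproduces identical files byte for byte.
#'
#' Group-level quantities can be supplied as overrides instead of being
#' estimated, which is how a published analysis whose group sample is
#' unavailable is reproduced: `trend` (model object or JSON path),
#' `weights` (object or JSON path), `mu`, and per-patient
#' `intercept_no_risk` (a single value or a named vector).
#'
#' An applicability score below `applicability_threshold` (or one that
#' cannot be computed, e.g. for a single-patient cohort) is logged as a
#' prominent warning but does not halt the run.
#'
#' @param cohort a [cohort()] object or path to a cohort CSV.
#' @param output_dir directory for artifacts (created if needed).
#' @param base_end_age,horizon_age the base/control split, see
#'   [split_trajectory()].
#' @param y_max index ceiling (default: the cohort's `value_max`).
#' @param patients patient ids to fit (default: all).
#' @param trend,weights,mu,intercept_no_risk optional overrides, see
#'   Details.
#' @param phi_convention passed to [compute_phi()].
#' @param selection_threshold passed to [factor_correlations()].
#' @param reference passed to [factor_correlations()].
#' @param bin_width correlation-grid bin width (months).
#' @param min_support passed to [correlation_function()].
#' @param applicability_threshold passed to [applicability_score()].
#' @param trend_control list of arguments forwarded to
#'   [fit_average_trend()] when the trend is not overridden.
#' @param eval_mode `"control"` (R-squared on the held-out window, the
#'   default) or `"all"` (all observations up to the horizon).
#' @param tol solver tolerance.
#' @param quiet suppress per-stage log messages.
#' @return The run report (also written as `report.json`), invisibly: a
#'   list with `settings`, `applicability`, `trend`, `weights`, `mu` and
#'   a per-patient list of `phi`, intercepts, amplitudes and evaluation
#'   metrics.
#' @export
run_pipeline <- function(cohort, output_dir, base_end_age, horizon_age,
                         y_max = NULL, patients = NULL,
                         trend = NULL, weights = NULL, mu = NULL,
                         intercept_no_risk = NULL,
                         phi_convention = "magnitude",
                         selection_threshold = 0.25,
                         reference = "initial",
                         bin_width = 15, min_support = 3L,
                         applicability_threshold = 0.7,
                         trend_control = list(),
                         eval_mode = c("control", "all"),
                         tol = 1e-9, quiet = FALSE) {
  eval_mode <- match.arg(eval_mode)
  log_msg <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(y_max)) y_max <- cohort$value_max
  if (is.null(patients)) patients <- patient_ids(cohort)
  dir.create(file.path(output_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)

  # --- average trend -------------------------------------------------
  trend_source <- "fitted"
  if (is.null(trend)) {
    trend <- do.call(fit_average_trend, c(list(cohort), trend_control))
    log_msg("trend", "fitted %d-term trend, pooled R^2 = %.4f",
            length(trend$rates),
            attr(trend, "diagnostics")$r_squared)
  } else {
    if (is.character(trend)) trend <- read_model(trend)
    trend_source <- "override"
    log_msg("trend", "using supplied trend with %d term(s)",
            length(trend$rates))
  }

  # --- applicability diagnostic -------------------------------------
  applicability <- tryCatch({
    slices <- bin_to_grid(cohort, time_grid_for(cohort, bin_width))
    surface <- suppressWarnings(correlation_function(slices, min_support))
    write_surface(surface, file.path(output_dir, "surface.csv"))
    score <- applicability_score(surface, applicability_threshold)
    list(score = as.numeric(score),
         applicable = attr(score, "applicable"),
         threshold = applicability_threshold)
  }, error = function(e) {
    list(score = NA_real_, applicable = NA, threshold = applicability_threshold,
         note = conditionMessage(e))
  })
  if (!isTRUE(applicability$applicable))
    warning(sprintf(
      "applicability diagnostic: %s (threshold %g); trajectories may not be similar enough for individual prediction",
      if (is.na(applicability$score)) "score undefined" else
        sprintf("score %.3f below threshold", applicability$score),
      applicability_threshold))
  log_msg("correlation", "applicability score: %s",
          if (is.na(applicability$score)) "undefined" else
            sprintf("%.3f", applicability$score))

  # --- risk factors and mu ------------------------------------------
  weights_source <- "fitted"
  if (is.null(weights)) {
    weights <- factor_correlations(cohort, reference = reference,
                                   selection_threshold = selection_threshold)
    log_msg("risk-factors", "retained %d factor(s)", nrow(weights$entries))
  } else {
    if (is.character(weights)) weights <- read_weights(weights)
    weights_source <- "override"
    log_msg("risk-factors", "using supplied weights (%d factor(s))",
            nrow(weights$entries))
  }
  mu_source <- "fitted"
  if (is.null(mu)) {
    mu <- as.numeric(estimate_mu(cohort, weights,
                                 convention = phi_convention))
    log_msg("mu", "estimated mu = %.4f", mu)
  } else {
    mu_source <- "override"
    log_msg("mu", "using supplied mu = %.4f", mu)
  }

  write_model(trend, file.path(output_dir, "trend.json"))
  write_weights(weights, file.path(output_dir, "weights.json"))

  # --- per-patient fits ---------------------------------------------
  a0_for <- function(id) {
    if (is.null(intercept_no_risk)) return(NULL)
    if (!is.null(names(intercept_no_risk))) {
      if (id %in% names(intercept_no_risk))
        return(unname(intercept_no_risk[[id]]))
      return(NULL)
    }
    as.numeric(intercept_no_risk)
  }

  patient_reports <- list()
  for (id in patients) {
    traj <- patient_trajectory(cohort, id)
    sp <- split_trajectory(traj, base_end_age, horizon_age)
    phi <- compute_phi(weights, traj$risk_indicators,
                       convention = phi_convention)
    fit <- fit_individual(sp$base, trend$rates, horizon_age, y_max = y_max,
                          phi = phi, mu = mu,
                          intercept_no_risk = a0_for(id), tol = tol)
    write_model(fit$model, file.path(output_dir, "models",
                                     paste0(id, ".json")))
    eval_obs <- switch(eval_mode,
                       control = sp$control,
                       all = rbind(sp$base, sp$control))
    report <- if (nrow(eval_obs))
      evaluate_prediction(fit$model, eval_obs)
    patient_reports[[id]] <- list(
      phi = phi$phi, signed_sum = phi$signed_sum,
      intercept_no_risk = fit$intercept_no_risk,
      intercept_source = if (is.null(fit$stage1)) "override" else "fitted",
      adjusted_intercept = fit$adjusted_intercept,
      amplitudes = fit$model$amplitudes,
      rates = fit$model$rates,
      stage2_objective = fit$stage2$objective,
      n_base = nrow(sp$base), n_control = nrow(sp$control),
      r_squared = if (is.null(report)) NA_real_ else report$r_squared,
      rmse = if (is.null(report)) NA_real_ else report$rmse)
    log_msg("fit", "%s: phi = %.3f, A0 = %.4f, R^2 = %s", id, phi$phi,
            fit$adjusted_intercept,
            if (is.null(report) || is.na(report$r_squared)) "NA" else
              sprintf("%.4f", report$r_squared))
  }

  report <- list(
    settings = list(base_end_age = base_end_age, horizon_age = horizon_age,
                    y_max = y_max, phi_convention = phi_convention,
                    eval_mode = eval_mode, bin_width = bin_width,
                    min_support = min_support,
                    applicability_threshold = applicability_threshold),
    applicability = applicability,
    trend = list(source = trend_source, intercept = trend$intercept,
                 amplitudes = trend$amplitudes, rates = trend$rates),
    weights = list(source = weights_source, entries = weights$entries),
    mu = list(source = mu_source, value = mu),
    patients = patient_reports
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       na = "null", dataframe = "rows")
  log_msg("done", "report written to %s", file.path(output_dir, "report.json"))
  invisible(report)
}

#' Run the pipeline from a YAML or JSON configuration file
#'
#' The configuration mirrors the arguments of [run_pipeline()]:
#' `cohort` (CSV path), `output_dir`, `base_end_age`, `horizon_age`, and
#' optionally `y_max`, `patients`, `trend` (model JSON path), `weights`
#' (weights JSON path), `mu`, `intercept_no_risk`, `phi_convention`,
#' `selection_threshold`, `reference`, `bin_width`, `min_support`,
#' `applicability_threshold`, `eval_mode`, `tol`. Paths are resolved
#' relative to the configuration file.
#'
#' @param path configuration file (`.yaml`, `.yml` or `.json`).
#' @param quiet passed to [run_pipeline()].
#' @return The run report, invisibly.
#' @export
run_pipeline_config <- function(path, quiet = FALSE) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  required <- c("cohort", "output_dir", "base_end_age", "horizon_age")
  absent <- setdiff(required, names(cfg))
  if (length(absent))
    stop("configuration lacks key(s): ", paste(absent, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  for (key in c("cohort", "output_dir", "trend", "weights"))
    if (!is.null(cfg[[key]])) cfg[[key]] <- resolve(cfg[[key]])
  if (!is.null(cfg$intercept_no_risk))
    cfg$intercept_no_risk <- unlist(cfg$intercept_no_risk)
  allowed <- setdiff(names(formals(run_pipeline)), "quiet")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(run_pipeline, c(cfg, list(quiet = quiet)))
}
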