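#' Risk-factor weights
#'
#' The weights \eqn{\delta_r} of the generalized perinatal/intranatal
#' factor \eqn{\Phi = \sum_r \delta_r P_r}: each is the (point-biserial)
#' correlation between a binary factor \eqn{P_r} and the motility index.
#' Usually produced by [factor_correlations()]; this constructor also
#' lets published weights be supplied directly.
#'
#' @param factors factor names (unique).
#' @param deltas correlations in `[-1, 1]`, one per factor.
#' @param selection_threshold minimum `|delta|` retained (recorded for
#'   provenance; entries below it are dropped).
#' @return An object of class `"factor_weights"` with a data frame
#'   `entries` (columns `factor`, `delta`, sorted by `|delta|`
#'   descending) and the `selection_threshold`.
#' @export
factor_weights <- function(factors, deltas, selection_threshold = 0.25) {
  factors <- as.character(factors)
  deltas <- as.numeric(deltas)
  if (length(factors) != length(deltas))
    stop("`factors` and `deltas` must have the same length")
  if (anyDuplicated(factors))
    stop("factor names must be unique")
  if (anyNA(deltas) || any(abs(deltas) > 1))
    stop("every delta must lie in [-1, 1]")
  keep <- abs(deltas) >= selection_threshold
  entries <- data.frame(factor = factors[keep], delta = deltas[keep],
                        stringsAsFactors = FALSE)
  entries <- entries[order(-abs(entries$delta)), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 selection_threshold = selection_threshold),
            class = "factor_weights")
}

#' @export
print.factor_weights <- function(x, ...) {
  cat(sprintf("<factor_weights> %d factor(s), |delta| >= %g\n",
              nrow(x$entries), x$selection_threshold))
  print(x$entries)
  invisible(x)
}

#' Select significant binary risk factors by correlation
#'
#' Computes, for every factor column of the cohort, the Pearson
#' correlation (point-biserial, the factors being binary) between the
#' indicator and a per-patient reference index value, drops factors whose
#' `|delta|` falls below `selection_threshold`, and sorts the survivors
#' by `|delta|`. Factors that are constant across patients have an
#' undefined correlation and are dropped with a warning.
#'
#' @param cohort a [cohort()] with factor columns.
#' @param reference which index value to correlate against:
#'   `"initial"` (each patient's earliest observed value, the default) or
#'   `"pooled"` (every visit contributes an observation-level row).
#' @param selection_threshold minimum `|delta|` retained (default 0.25).
#' @return A [factor_weights()] object; the number of candidate factors
#'   screened is recorded in the `n_candidates` attribute.
#' @export
factor_correlations <- function(cohort,
                                reference = c("initial", "pooled"),
                                selection_threshold = 0.25) {
  stopifnot(inherits(cohort, "cohort"))
  reference <- match.arg(reference)
  if (!length(cohort$factor_names))
    stop("cohort has no risk-factor columns")
  fac <- cohort$factors
  obs <- cohort$observations
  if (reference == "initial") {
    first <- do.call(rbind, lapply(split(obs, obs$patient_id), function(d)
      d[which.min(d$age_months), c("patient_id", "value")]))
    tab <- merge(fac, first, by = "patient_id")
  } else {
    tab <- merge(fac, obs[, c("patient_id", "value")], by = "patient_id")
  }
  if (length(unique(tab$patient_id)) < 3L)
    stop("need at least 3 patients with both factor data and an index value")
  deltas <- vapply(cohort$factor_names, function(fn) {
    v <- tab[[fn]]
    if (stats::var(v) <= 0) {
      warning(sprintf("factor '%s' is constant; correlation undefined, dropped", fn))
      return(NA_real_)
    }
    stats::cor(v, tab$value)
  }, 0)
  defined <- !is.na(deltas)
  fw <- factor_weights(cohort$factor_names[defined], deltas[defined],
                       selection_threshold = selection_threshold)
  attr(fw, "n_candidates") <- length(cohort$factor_names)
  fw
}

#' Generalized risk factor of a patient
#'
#' \eqn{\Phi = \sum_r \delta_r P_r}, the correlation-weighted sum of a
#' patient's binary risk indicators. Because adverse factors correlate
#' negatively with the index, the signed sum is negative for an affected
#' patient; under the default `"magnitude"` convention \eqn{\Phi} is its
#' absolute value, the scale on which the intercept-adjustment slope
#' \eqn{\mu} (itself negative) is defined. The `"signed"` convention
#' returns the raw sum.
#'
#' @param weights a [factor_weights()] object.
#' @param indicators named 0/1 vector (or list) with one entry per
#'   weighted factor.
#' @param convention `"magnitude"` (default) or `"signed"`.
#' @return An object of class `"phi_result"`: `phi`, `signed_sum`,
#'   per-factor `contributions`, and the `convention` used.
#' @export
compute_phi <- function(weights, indicators,
                        convention = c("magnitude", "signed")) {
  stopifnot(inherits(weights, "factor_weights"))
  convention <- match.arg(convention)
  indicators <- unlist(indicators)
  missing <- setdiff(weights$entries$factor, names(indicators))
  if (length(missing))
    stop("missing indicator(s) for factor(s): ",
         paste(missing, collapse = ", "))
  p <- as.numeric(indicators[weights$entries$factor])
  if (anyNA(p) || !all(p %in% c(0, 1)))
    stop("indicators must be binary (0/1)")
  contributions <- stats::setNames(weights$entries$delta * p,
                                   weights$entries$factor)
  signed_sum <- sum(contributions)
  phi <- if (convention == "magnitude") abs(signed_sum) else signed_sum
  structure(list(phi = phi, signed_sum = signed_sum,
                 contributions = contributions, convention = convention),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("<phi_result> phi = %g (%s convention; signed sum %g)\n",
              x$phi, x$convention, x$signed_sum))
  invisible(x)
}

#' Estimate the intercept-adjustment slope
#'
#' Ordinary-least-squares slope \eqn{\mu} of the initial index value on
#' the generalized factor \eqn{\Phi} across the cohort's patients; the
#' regression intercept is discarded. \eqn{\mu} measures how strongly the
#' perinatal/intranatal factors depress the index at the initial time and
#' is used to shift a patient's fitted intercept:
#' \eqn{A_0 = A_0|_{\Phi=0} + \mu\Phi}.
#'
#' @param cohort a [cohort()] with factor columns.
#' @param weights a [factor_weights()] object.
#' @param initial_rule which value stands for the "index at the initial
#'   time": `"first_observation"` (each patient's earliest observed
#'   value, the default) or `"fitted_intercept"` (the patient's stage-1
#'   fitted intercept, which requires `rates`, `base_end_age`,
#'   `horizon_age`).
#' @param convention passed to [compute_phi()].
#' @param rates,base_end_age,horizon_age,y_max needed only for
#'   `initial_rule = "fitted_intercept"`.
#' @return Scalar slope `mu` (index units per unit of `Phi`) with
#'   attributes `n` (patients used) and `intercept` (the discarded OLS
#'   intercept).
#' @export
estimate_mu <- function(cohort, weights,
                        initial_rule = c("first_observation",
                                         "fitted_intercept"),
                        convention = "magnitude",
                        rates = NULL, base_end_age = NULL,
                        horizon_age = NULL, y_max = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(weights, "factor_weights"))
  initial_rule <- match.arg(initial_rule)
  ids <- patient_ids(cohort)
  if (is.null(y_max)) y_max <- cohort$value_max

  rows <- lapply(ids, function(id) {
    traj <- patient_trajectory(cohort, id)
    if (!length(traj$risk_indicators)) return(NULL)
    phi <- compute_phi(weights, traj$risk_indicators,
                       convention = convention)$phi
    y0 <- if (initial_rule == "first_observation") {
      traj$observations$value[which.min(traj$observations$age_months)]
    } else {
      if (is.null(rates) || is.null(base_end_age) || is.null(horizon_age))
        stop("fitted_intercept rule needs rates, base_end_age and horizon_age")
      sp <- split_trajectory(traj, base_end_age, horizon_age)
      fit <- solve_active_set(build_problem(sp$base, rates, horizon_age,
                                            y_max = y_max))
      unname(fit$coefficients[1L])
    }
    c(phi = phi, y0 = y0)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3L)
    stop("need at least 3 patients with factor data")
  if (stats::var(tab[, "phi"]) <= 0)
    stop("mu unidentifiable: Phi is constant across patients")
  fit <- stats::lm(y0 ~ phi, data = as.data.frame(tab))
  structure(unname(stats::coef(fit)[2L]),
            n = nrow(tab), intercept = unname(stats::coef(fit)[1L]))
}

#' Write / read factor weights as JSON
#'
#' Schema: `{format_version, selection_threshold, entries:
#' [{factor, delta}]}` at full precision; round-trip exact.
#'
#' @param weights a [factor_weights()] object.
#' @param path JSON file path.
#' @return `write_weights` returns `path` invisibly; `read_weights` the
#'   reconstructed [factor_weights()].
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "factor_weights"))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    selection_threshold = weights$selection_threshold,
    entries = lapply(seq_len(nrow(weights$entries)), function(i)
      list(factor = weights$entries$factor[i],
           delta = weights$entries$delta[i]))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$format_version) ||
      !identical(as.character(payload$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported or missing weights format_version in ", path)
  factor_weights(
    vapply(payload$entries, function(e) as.character(e$factor), ""),
    vapply(payload$entries, function(e) as.numeric(e$delta), 0),
    selection_threshold = as.numeric(payload$selection_threshold)
  )
}
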