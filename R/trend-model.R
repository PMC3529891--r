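#' Saturating-exponential trend model
#'
#' The model family used both for the cohort-average trend
#' \deqn{f(t) = a_0 + \sum_{q=1}^{Q} a_q (1 - e^{-\lambda_q t})}
#' and for the individual trend \eqn{F(t)}, which shares the cohort decay
#' rates \eqn{\lambda_q} but has patient-specific intercept and
#' amplitudes. Each term rises from 0 at \eqn{t = 0} towards its
#' amplitude, so the curve starts at the intercept and saturates at
#' `intercept + sum(amplitudes)`.
#'
#' @param intercept value at \eqn{t = 0} (index units).
#' @param amplitudes term amplitudes (index units); must be non-negative
#'   when `monotone = TRUE`.
#' @param rates positive decay rates (per month), same length as
#'   `amplitudes`.
#' @param monotone flag a model whose amplitudes are constrained
#'   non-negative, making it non-decreasing in age (the individual-model
#'   case: skills accumulate and loss is not modelled).
#' @param bounds optional length-2 numeric, the index scale bounds carried
#'   along for serialization (not enforced on model values).
#' @return An object of class `"exp_trend"`.
#' @examples
#' m <- exp_trend(-16.49, c(66.87, 28.39), c(0.01, 0.09))
#' predict(m, c(0, 15, 105))
#' asymptote(m)
#' @export
exp_trend <- function(intercept, amplitudes = numeric(), rates = numeric(),
                      monotone = FALSE, bounds = NULL) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("`intercept` must be a finite scalar")
  amplitudes <- as.numeric(amplitudes)
  rates <- as.numeric(rates)
  if (length(amplitudes) != length(rates))
    stop("`amplitudes` and `rates` must have the same length")
  if (anyNA(amplitudes) || anyNA(rates) || any(!is.finite(amplitudes)) ||
      any(!is.finite(rates)))
    stop("amplitudes and rates must be finite")
  if (any(rates <= 0))
    stop("every rate must be > 0 (per month)")
  if (isTRUE(monotone) && any(amplitudes < 0))
    stop("monotone models require non-negative amplitudes")
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    if (length(bounds) != 2L || anyNA(bounds) || bounds[1L] >= bounds[2L])
      stop("`bounds` must be c(min, max) with min < max")
  }
  structure(
    list(intercept = intercept, amplitudes = amplitudes, rates = rates,
         monotone = isTRUE(monotone), bounds = bounds),
    class = "exp_trend"
  )
}

#' Evaluate a trend model at given ages
#'
#' Exact closed-form evaluation
#' `intercept + sum(amplitudes * (1 - exp(-rates * t)))`.
#'
#' @param object an [exp_trend()] model.
#' @param t ages in months, all non-negative.
#' @param ... unused.
#' @return Numeric vector of index values, one per age.
#' @export
predict.exp_trend <- function(object, t, ...) {
  t <- as.numeric(t)
  if (length(t) == 0L) return(numeric(0))
  if (anyNA(t) || any(t < 0))
    stop("ages must be non-negative")
  q <- length(object$rates)
  if (q == 0L) return(rep(object$intercept, length(t)))
  growth <- 1 - exp(-outer(t, object$rates))          # |t| x Q
  drop(object$intercept + growth %*% object$amplitudes)
}

#' Asymptote of a trend model
#'
#' The limit of the model as age grows without bound:
#' `intercept + sum(amplitudes)`.
#'
#' @param model an [exp_trend()] model.
#' @return A finite scalar.
#' @export
asymptote <- function(model) {
  stopifnot(inherits(model, "exp_trend"))
  model$intercept + sum(model$amplitudes)
}

#' @export
print.exp_trend <- function(x, digits = 4, ...) {
  terms <- if (length(x$rates))
    paste(sprintf("%s(1 - exp(-%s t))",
                  format(x$amplitudes, digits = digits, trim = TRUE),
                  format(x$rates, digits = digits, trim = TRUE)),
          collapse = " + ")
  else "(no exponential terms)"
  cat(sprintf("<exp_trend%s> F(t) = %s + %s\n",
              if (x$monotone) ", monotone" else "",
              format(x$intercept, digits = digits), terms))
  cat(sprintf("  asymptote %s\n", format(asymptote(x), digits = digits)))
  invisible(x)
}

MODEL_FORMAT_VERSION <- "1.0"

#' Write / read a trend model as JSON
#'
#' The on-disk schema is
#' `{format_version, intercept, terms: [{amplitude, rate}], monotone,
#' bounds: {min, max}}` with full-precision numbers, so
#' `read_model(write_model(m))` reproduces every field exactly.
#'
#' @param model an [exp_trend()] model.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the reconstructed [exp_trend()] model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "exp_trend"))
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    intercept = model$intercept,
    terms = lapply(seq_along(model$rates), function(i)
      list(amplitude = model$amplitudes[i], rate = model$rates[i])),
    monotone = model$monotone
  )
  if (!is.null(model$bounds))
    payload$bounds <- list(min = model$bounds[1L], max = model$bounds[2L])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$format_version) ||
      !identical(as.character(payload$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported or missing model format_version in ", path)
  amps <- vapply(payload$terms, function(tr) as.numeric(tr$amplitude), 0)
  rates <- vapply(payload$terms, function(tr) as.numeric(tr$rate), 0)
  bounds <- if (!is.null(payload$bounds))
    c(as.numeric(payload$bounds$min), as.numeric(payload$bounds$max))
  exp_trend(as.numeric(payload$intercept), amps, rates,
            monotone = isTRUE(payload$monotone), bounds = bounds)
}
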