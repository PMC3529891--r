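#' Assemble a longitudinal cohort
#'
#' A cohort bundles long-format index observations (one row per patient
#' visit) with an optional roster of binary perinatal/intranatal risk
#' factors (one row per patient) and the bounds of the index scale.
#'
#' @param observations data frame with columns `patient_id`, `age_months`
#'   (non-negative, months) and `value` (index score within the bounds).
#' @param factors optional data frame with a `patient_id` column and one
#'   column per binary risk factor; entries must be 0 or 1, one row per
#'   patient, patient ids a subset of those in `observations`.
#' @param value_min,value_max bounds of the index scale. The default
#'   `[0, 60]` is the range of a 12-skill, five-point expert motility
#'   score; override for other indices.
#'
#' @return An object of class `"cohort"`: a list with elements
#'   `observations` (sorted by patient then age), `factors`,
#'   `factor_names`, `value_min`, `value_max`.
#' @seealso [read_cohort()], [patient_trajectory()], [split_trajectory()]
#' @export
cohort <- function(observations, factors = NULL, value_min = 0, value_max = 60) {
  if (!is.data.frame(observations))
    stop("`observations` must be a data frame")
  required <- c("patient_id", "age_months", "value")
  absent <- setdiff(required, names(observations))
  if (length(absent))
    stop("observations lack column(s): ", paste(absent, collapse = ", "))
  if (nrow(observations) == 0L)
    stop("no observations")
  if (!is.numeric(value_min) || !is.numeric(value_max) ||
      length(value_min) != 1L || length(value_max) != 1L ||
      !is.finite(value_min) || !is.finite(value_max) || value_min >= value_max)
    stop("`value_min` must be finite and smaller than `value_max`")

  obs <- data.frame(
    patient_id = as.character(observations$patient_id),
    age_months = as.numeric(observations$age_months),
    value      = as.numeric(observations$value),
    stringsAsFactors = FALSE
  )
  if (anyNA(obs))
    stop("observations contain missing values")
  if (any(obs$age_months < 0))
    stop("ages must be non-negative (months)")
  bad <- which(obs$value < value_min | obs$value > value_max)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("value %g outside index bounds [%g, %g] (patient %s, age %g)",
                 obs$value[b], value_min, value_max,
                 obs$patient_id[b], obs$age_months[b]))
  }
  dup <- which(duplicated(obs[c("patient_id", "age_months")]))
  if (length(dup)) {
    d <- dup[1L]
    stop(sprintf("duplicate (patient, age) pair: (%s, %g)",
                 obs$patient_id[d], obs$age_months[d]))
  }
  obs <- obs[order(obs$patient_id, obs$age_months), , drop = FALSE]
  rownames(obs) <- NULL
  ids <- unique(obs$patient_id)

  fac <- NULL
  factor_names <- character()
  if (!is.null(factors)) {
    if (!is.data.frame(factors) || !"patient_id" %in% names(factors))
      stop("`factors` must be a data frame with a `patient_id` column")
    factor_names <- setdiff(names(factors), "patient_id")
    fac <- factors[, c("patient_id", factor_names), drop = FALSE]
    fac$patient_id <- as.character(fac$patient_id)
    if (anyDuplicated(fac$patient_id))
      stop("`factors` must have one row per patient")
    unknown <- setdiff(fac$patient_id, ids)
    if (length(unknown))
      stop("factor rows for unknown patient(s): ", paste(unknown, collapse = ", "))
    for (fn in factor_names) {
      v <- fac[[fn]]
      if (anyNA(v) || !all(v %in% c(0, 1)))
        stop(sprintf("factor column '%s' must be binary (0/1)", fn))
      fac[[fn]] <- as.numeric(v)
    }
    fac <- fac[order(fac$patient_id), , drop = FALSE]
    rownames(fac) <- NULL
  }

  structure(
    list(observations = obs, factors = fac, factor_names = factor_names,
         value_min = value_min, value_max = value_max),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  ids <- unique(x$observations$patient_id)
  cat(sprintf("<cohort> %d patients, %d observations, index bounds [%g, %g]\n",
              length(ids), nrow(x$observations), x$value_min, x$value_max))
  if (length(x$factor_names))
    cat("  risk factors:", paste(x$factor_names, collapse = ", "), "\n")
  invisible(x)
}

#' Patient ids of a cohort
#' @param cohort a [cohort()] object.
#' @return Character vector of unique patient identifiers.
#' @export
patient_ids <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  unique(cohort$observations$patient_id)
}

#' Read a cohort from CSV
#'
#' The canonical dialect is comma-separated UTF-8 with a header row and
#' `.` as decimal separator. Required columns: `patient_id`, `age_months`,
#' `value`. Any additional column is interpreted as a binary risk-factor
#' indicator that must be constant within a patient.
#'
#' @param path path to the CSV file.
#' @param value_min,value_max index bounds, as in [cohort()].
#' @return A [cohort()] object.
#' @export
read_cohort <- function(path, value_min = 0, value_max = 60) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  required <- c("patient_id", "age_months", "value")
  absent <- setdiff(required, names(raw))
  if (length(absent))
    stop("CSV lacks column(s): ", paste(absent, collapse = ", "))
  if (nrow(raw) == 0L)
    stop("no observations in ", path)
  # data line numbers: header is line 1
  line_no <- seq_len(nrow(raw)) + 1L

  if (anyNA(raw$age_months) || anyNA(raw$value))
    stop(sprintf("missing age/value on line(s) %s",
                 paste(line_no[is.na(raw$age_months) | is.na(raw$value)],
                       collapse = ", ")))
  bad <- which(raw$value < value_min | raw$value > value_max)
  if (length(bad))
    stop(sprintf("value outside index bounds [%g, %g] on line(s) %s",
                 value_min, value_max, paste(line_no[bad], collapse = ", ")))
  dup <- which(duplicated(raw[c("patient_id", "age_months")]))
  if (length(dup))
    stop(sprintf("duplicate (patient, age) pair (%s, %g) on line %d",
                 raw$patient_id[dup[1L]], raw$age_months[dup[1L]],
                 line_no[dup[1L]]))

  factor_names <- setdiff(names(raw), required)
  fac <- NULL
  if (length(factor_names)) {
    for (fn in factor_names) {
      v <- raw[[fn]]
      bad <- which(is.na(v) | !(v %in% c(0, 1)))
      if (length(bad))
        stop(sprintf("non-binary entry in factor column '%s' on line(s) %s",
                     fn, paste(line_no[bad], collapse = ", ")))
    }
    per <- unique(raw[, c("patient_id", factor_names), drop = FALSE])
    if (anyDuplicated(per$patient_id)) {
      pid <- per$patient_id[duplicated(per$patient_id)][1L]
      stop(sprintf("factor indicators vary within patient %s", pid))
    }
    fac <- per
  }
  cohort(raw[, required], factors = fac,
         value_min = value_min, value_max = value_max)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: factor indicators are repeated on every
#' observation row of the patient. `read_cohort(write_cohort(...))`
#' reproduces every (patient, age, value, factors) tuple exactly.
#'
#' @param cohort a [cohort()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort$observations
  if (length(cohort$factor_names))
    out <- merge(out, cohort$factors, by = "patient_id", sort = FALSE)
  out <- out[order(out$patient_id, out$age_months), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one patient's trajectory
#'
#' @param cohort a [cohort()] object.
#' @param patient_id the patient to extract.
#' @return A list of class `"patient_trajectory"` with `patient_id`,
#'   `observations` (data frame `age_months`, `value`, ages strictly
#'   increasing) and `risk_indicators` (named 0/1 vector, possibly empty).
#' @export
patient_trajectory <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "cohort"))
  obs <- cohort$observations
  sel <- obs[obs$patient_id == patient_id, c("age_months", "value")]
  if (nrow(sel) == 0L)
    stop("unknown patient: ", patient_id)
  rownames(sel) <- NULL
  ind <- numeric(0)
  if (!is.null(cohort$factors)) {
    row <- cohort$factors[cohort$factors$patient_id == patient_id, , drop = FALSE]
    if (nrow(row) == 1L) {
      ind <- as.numeric(row[1L, cohort$factor_names])
      names(ind) <- cohort$factor_names
    }
  }
  structure(list(patient_id = patient_id, observations = sel,
                 risk_indicators = ind),
            class = "patient_trajectory")
}

#' Split a trajectory into base and control periods
#'
#' The early "base" window (age at or below `base_end_age`) is used to fit
#' the individual model; the later "control" window (ages up to the
#' prediction horizon) is held out to test the prediction.
#'
#' @param traj a `"patient_trajectory"` or a data frame with columns
#'   `age_months` and `value`.
#' @param base_end_age last age (months) included in the base period.
#' @param horizon_age prediction horizon (months); must exceed
#'   `base_end_age`.
#' @param include_beyond_horizon if `TRUE`, observations past the horizon
#'   are kept in the control period instead of being dropped.
#' @return A list with data frames `base` and `control` (order preserved,
#'   no observation at or below the horizon dropped or duplicated).
#' @export
split_trajectory <- function(traj, base_end_age, horizon_age,
                             include_beyond_horizon = FALSE) {
  obs <- if (inherits(traj, "patient_trajectory")) traj$observations else traj
  if (!is.data.frame(obs) || !all(c("age_months", "value") %in% names(obs)))
    stop("`traj` must be a patient_trajectory or a data frame with age_months/value")
  if (!is.numeric(base_end_age) || !is.numeric(horizon_age) ||
      base_end_age <= 0 || horizon_age <= base_end_age)
    stop("need 0 < base_end_age < horizon_age")
  base <- obs[obs$age_months <= base_end_age, , drop = FALSE]
  keep <- obs$age_months > base_end_age
  if (!include_beyond_horizon)
    keep <- keep & obs$age_months <= horizon_age
  control <- obs[keep, , drop = FALSE]
  if (nrow(base) == 0L)
    stop("no base-period observations")
  rownames(base) <- rownames(control) <- NULL
  list(base = base, control = control)
}
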