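#' Age grid for time-slice analysis
#'
#' Defines the time slices over which the empirical correlation function
#' of the longitudinal process is computed. Visits falling inside a bin
#' are treated as observations of that slice.
#'
#' @param bin_edges strictly increasing ages (months), at least three
#'   values (two bins).
#' @param bin_centers representative age per bin; defaults to midpoints.
#' @return An object of class `"time_grid"`.
#' @export
time_grid <- function(bin_edges, bin_centers = NULL) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 3L || any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly increasing with at least 2 bins")
  if (is.null(bin_centers))
    bin_centers <- (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2
  bin_centers <- as.numeric(bin_centers)
  if (length(bin_centers) != length(bin_edges) - 1L)
    stop("need one center per bin")
  structure(list(bin_edges = bin_edges, bin_centers = bin_centers),
            class = "time_grid")
}

#' Equal-width age grid covering a cohort
#'
#' Bins are centered on multiples of `bin_width`, so a visit schedule
#' aligned on that spacing (e.g. 15, 30, ..., 105 months with the
#' default width) maps each visit to its own slice.
#'
#' @param cohort a [cohort()] object.
#' @param bin_width bin width in months (default 15, the spacing of a
#'   typical 9-year visit schedule with 7 visits).
#' @return A [time_grid()] whose bins cover every observed age.
#' @export
time_grid_for <- function(cohort, bin_width = 15) {
  stopifnot(inherits(cohort, "cohort"), bin_width > 0)
  ages <- cohort$observations$age_months
  lo <- round(min(ages) / bin_width)
  hi <- round(max(ages) / bin_width)
  if (hi == lo) hi <- lo + 1L
  centers <- seq(lo, hi) * bin_width
  time_grid(c(centers - bin_width / 2, centers[length(centers)] + bin_width / 2),
            bin_centers = centers)
}

#' Bin observations onto a time grid
#'
#' Builds the per-patient slice table: one row per patient, one column
#' per bin. A patient contributes at most one value per bin (the mean of
#' their observations falling in it); empty bins are `NA`. Bins are
#' left-closed, the last bin also right-closed.
#'
#' @param cohort a [cohort()] object.
#' @param grid a [time_grid()].
#' @return Numeric matrix (patients x bins) with patient ids as row names
#'   and bin centers as column names, plus a `grid` attribute.
#' @export
bin_to_grid <- function(cohort, grid) {
  stopifnot(inherits(cohort, "cohort"), inherits(grid, "time_grid"))
  ids <- patient_ids(cohort)
  nb <- length(grid$bin_centers)
  slices <- matrix(NA_real_, length(ids), nb,
                   dimnames = list(ids, format(grid$bin_centers, trim = TRUE)))
  obs <- cohort$observations
  idx <- findInterval(obs$age_months, grid$bin_edges, rightmost.closed = TRUE)
  ok <- idx >= 1L & idx <= nb
  if (any(ok)) {
    agg <- stats::aggregate(value ~ patient_id + bin,
                            data = data.frame(patient_id = obs$patient_id[ok],
                                              bin = idx[ok],
                                              value = obs$value[ok]),
                            FUN = mean)
    slices[cbind(match(agg$patient_id, ids), agg$bin)] <- agg$value
  }
  attr(slices, "grid") <- grid
  slices
}

#' Empirical correlation function of the longitudinal process
#'
#' For every pair of time slices \eqn{(t, t')} computes the Pearson
#' correlation across patients observed in *both* slices
#' (pairwise-complete):
#' \deqn{r_y(t, t') = \frac{M[\mathring{Y}(t)\,\mathring{Y}(t')]}
#' {\sqrt{D_y(t) D_y(t')}},}
#' where \eqn{\mathring{Y}} is the slice centred on its across-patient
#' mean and \eqn{D_y} the slice variance (n-1 denominator; the
#' correlation is invariant to that choice). Entries supported by fewer
#' than `min_support` patients, or with zero variance in either slice,
#' are undefined (`NA`).
#'
#' @param slices patient-by-bin matrix from [bin_to_grid()].
#' @param min_support minimum number of patients per pair (default 3;
#'   a Pearson correlation on fewer points is meaningless).
#' @return An object of class `"correlation_surface"`: `values`
#'   (symmetric matrix, unit diagonal where defined), `support_counts`,
#'   and the originating `grid`.
#' @export
correlation_function <- function(slices, min_support = 3L) {
  stopifnot(is.matrix(slices))
  if (min_support < 3L)
    stop("`min_support` must be at least 3")
  nb <- ncol(slices)
  vals <- matrix(NA_real_, nb, nb, dimnames = list(colnames(slices),
                                                   colnames(slices)))
  supp <- matrix(0L, nb, nb, dimnames = dimnames(vals))
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      both <- stats::complete.cases(slices[, c(i, j), drop = FALSE])
      n <- sum(both)
      supp[i, j] <- supp[j, i] <- n
      if (n < min_support) next
      xi <- slices[both, i]
      xj <- slices[both, j]
      if (stats::var(xi) <= 0 || stats::var(xj) <= 0) next
      r <- if (i == j) 1 else stats::cor(xi, xj)
      vals[i, j] <- vals[j, i] <- r
    }
  }
  if (all(is.na(vals)))
    warning("no slice pair reaches min_support; surface is all-undefined")
  structure(list(values = vals, support_counts = supp,
                 grid = attr(slices, "grid")),
            class = "correlation_surface")
}

#' @export
print.correlation_surface <- function(x, ...) {
  nb <- ncol(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<correlation_surface> %d bins, %d/%d off-diagonal entries defined\n",
              nb, sum(!is.na(off)), length(off)))
  if (any(!is.na(off)))
    cat(sprintf("  off-diagonal range [%.3f, %.3f]\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Method-applicability score of a correlation surface
#'
#' The individual-prediction method assumes patient trajectories are
#' near-affine copies of one another, i.e. a between-age correlation
#' function close to one. This score is the support-weighted mean of the
#' defined off-diagonal entries; values above `threshold` flag the
#' method as applicable. The threshold is a diagnostic convention, not a
#' hard gate.
#'
#' @param surface a [correlation_function()] result.
#' @param threshold applicability threshold (default 0.7).
#' @return Scalar score in `[-1, 1]` with attributes `applicable`
#'   (logical) and `threshold`.
#' @export
applicability_score <- function(surface, threshold = 0.7) {
  stopifnot(inherits(surface, "correlation_surface"))
  up <- upper.tri(surface$values)
  r <- surface$values[up]
  w <- surface$support_counts[up]
  ok <- !is.na(r)
  if (!any(ok))
    stop("no defined off-diagonal entries")
  score <- sum(r[ok] * w[ok]) / sum(w[ok])
  structure(score, applicable = score >= threshold, threshold = threshold)
}

#' Write a correlation surface as CSV
#'
#' Symmetric matrix with bin centers as header row and first column;
#' undefined entries are empty cells.
#'
#' @param surface a [correlation_function()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "correlation_surface"))
  m <- surface$values
  df <- data.frame(bin_center = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
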