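#' Constrained least-squares problem for an individual trajectory
#'
#' Low-level constructor. The problem is
#' \deqn{\min_A \| X A - y \|^2 \quad \text{s.t.}\quad A_i \ge 0\ (i \in
#' \text{nonneg}),\quad c^\top A \le y_{\max},}
#' the quadratic program behind the individual-model identification:
#' non-negative amplitudes enforce monotone skill accumulation and the
#' ceiling row keeps the model at or below the top of the index scale at
#' the prediction horizon.
#'
#' @param design numeric matrix `X` (one row per base-period observation).
#' @param targets numeric vector `y`, same length as `nrow(design)`.
#' @param nonneg integer indices of columns constrained non-negative.
#' @param ceiling numeric vector `c` (length `ncol(design)`) of the
#'   ceiling constraint, or `NULL` for none.
#' @param y_max right-hand side of the ceiling constraint (`Inf` disables
#'   it).
#' @param fixed_intercept metadata: the intercept value already absorbed
#'   into `targets` (or `NULL` when the intercept column is part of the
#'   design). Carried along so solutions can be mapped back to a model.
#' @param rates,t_horizon,ages optional metadata describing how the
#'   matrices were built (see [build_problem()]).
#' @return An object of class `"cfit_problem"`.
#' @seealso [build_problem()], [solve_active_set()], [solve_oracle()]
#' @export
cfit_problem <- function(design, targets, nonneg = integer(),
                         ceiling = NULL, y_max = Inf,
                         fixed_intercept = NULL, rates = NULL,
                         t_horizon = NULL, ages = NULL) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  targets <- as.numeric(targets)
  if (nrow(design) != length(targets))
    stop("design rows and targets length differ")
  if (nrow(design) < 1L)
    stop("need at least one observation")
  nonneg <- as.integer(nonneg)
  if (length(nonneg) && (any(nonneg < 1L) || any(nonneg > ncol(design))))
    stop("`nonneg` indices out of range")
  if (!is.null(ceiling)) {
    ceiling <- as.numeric(ceiling)
    if (length(ceiling) != ncol(design))
      stop("`ceiling` must have one entry per design column")
    if (!is.finite(y_max))
      ceiling <- NULL                    # an infinite ceiling never binds
  }
  if (is.null(colnames(design)))
    colnames(design) <- paste0("A", seq_len(ncol(design)) - 1L)
  gram <- crossprod(design)
  full_rank <- qr(design)$rank == ncol(design) &&
    (ncol(design) == 1L || rcond(gram) > 1e-10)
  # A (near-)rank-deficient design has multiple least-squares minimizers.
  # A vanishing Tikhonov term makes the QP strictly convex and selects
  # the minimum-norm one deterministically; solutions are flagged
  # `non_unique`.
  ridge <- if (full_rank) 0 else 1e-6 * max(mean(diag(gram)), 1)
  structure(
    list(design = design, targets = targets, nonneg = nonneg,
         ceiling = ceiling, y_max = y_max, fixed_intercept = fixed_intercept,
         rates = rates, t_horizon = t_horizon, ages = ages,
         full_rank = full_rank, ridge = ridge),
    class = "cfit_problem"
  )
}

#' Build the constrained fit problem from base-period observations
#'
#' Assembles the design matrix with entries \eqn{1 - e^{-\lambda_q
#' t_\gamma}} (plus an all-ones intercept column when the intercept is
#' free), the ceiling row evaluated at the prediction horizon, and the
#' non-negativity set covering every amplitude column. When
#' `fixed_intercept` is supplied the intercept column is removed, the
#' targets become `y - A0`, and the ceiling right-hand side becomes
#' `y_max - A0`.
#'
#' @param base_obs data frame of base-period observations with columns
#'   `age_months` and `value` (as produced by [split_trajectory()]).
#' @param rates positive decay rates \eqn{\lambda_q} identified from the
#'   cohort-average trend.
#' @param t_horizon prediction horizon (months) at which the ceiling is
#'   enforced.
#' @param y_max highest possible index value (default 60).
#' @param fixed_intercept optional fixed intercept \eqn{A_0} (the
#'   risk-adjusted value in stage 2 of [fit_individual()]).
#' @return A [cfit_problem()].
#' @export
build_problem <- function(base_obs, rates, t_horizon, y_max = 60,
                          fixed_intercept = NULL) {
  if (!is.data.frame(base_obs) ||
      !all(c("age_months", "value") %in% names(base_obs)))
    stop("`base_obs` must have columns age_months and value")
  if (nrow(base_obs) == 0L)
    stop("no base-period observations")
  rates <- as.numeric(rates)
  if (length(rates) == 0L || any(rates <= 0))
    stop("`rates` must be positive and non-empty")
  if (!is.numeric(t_horizon) || t_horizon <= 0)
    stop("`t_horizon` must be a positive age in months")
  tg <- as.numeric(base_obs$age_months)
  y <- as.numeric(base_obs$value)
  growth <- 1 - exp(-outer(tg, rates))                 # Theta0 x Q
  colnames(growth) <- paste0("A", seq_along(rates))
  chor <- 1 - exp(-rates * t_horizon)
  if (is.null(fixed_intercept)) {
    design <- cbind(A0 = 1, growth)
    cfit_problem(design, y, nonneg = seq_along(rates) + 1L,
                 ceiling = c(1, chor), y_max = y_max,
                 rates = rates, t_horizon = t_horizon, ages = tg)
  } else {
    cfit_problem(growth, y - fixed_intercept, nonneg = seq_along(rates),
                 ceiling = chor, y_max = y_max - fixed_intercept,
                 fixed_intercept = fixed_intercept,
                 rates = rates, t_horizon = t_horizon, ages = tg)
  }
}

# Inequality constraints of a problem in the form G x <= h.
constraint_system <- function(problem) {
  p <- ncol(problem$design)
  G <- matrix(0, 0, p)
  h <- numeric(0)
  nm <- character(0)
  for (i in problem$nonneg) {
    row <- rep(0, p); row[i] <- -1
    G <- rbind(G, row); h <- c(h, 0)
    nm <- c(nm, paste0("nonneg:", colnames(problem$design)[i]))
  }
  if (!is.null(problem$ceiling)) {
    G <- rbind(G, problem$ceiling); h <- c(h, problem$y_max)
    nm <- c(nm, "ceiling")
  }
  rownames(G) <- nm
  list(G = G, h = h, names = nm)
}

# Equality-constrained least squares via its KKT linear system:
#   [2X'X  E'] [z ]   [2X'y]
#   [E     0 ] [nu] = [d   ]
# Uses an exact solve when the system is non-singular, otherwise a
# min-norm pseudoinverse solve (deterministic tie-break for
# rank-deficient designs).
kkt_solve <- function(XtX2, Xty2, E, d) {
  p <- ncol(XtX2)
  k <- nrow(E)
  M <- rbind(cbind(XtX2, t(E)), cbind(E, matrix(0, k, k)))
  rhs <- c(Xty2, d)
  exact <- rcond(M) > 1e-13
  sol <- if (exact)
    tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    exact <- FALSE
    sol <- drop(MASS::ginv(M) %*% rhs)
  }
  resid <- max(abs(M %*% sol - rhs))
  list(z = sol[seq_len(p)], nu = if (k) sol[p + seq_len(k)] else numeric(0),
       consistent = resid <= 1e-7 * max(1, max(abs(rhs))),
       exact = exact)
}

fit_result <- function(x, problem, cs, active, multipliers, converged,
                       iterations, method, tol) {
  X <- problem$design
  r <- drop(X %*% x) - problem$targets
  grad <- 2 * (drop(crossprod(X, r)) + problem$ridge * x)
  lam_full <- rep(0, length(cs$h))
  lam_full[active] <- multipliers
  kkt_resid <- if (length(cs$h))
    max(abs(grad + drop(crossprod(cs$G, lam_full)))) else max(abs(grad))
  coef <- x
  names(coef) <- colnames(X)
  structure(
    list(coefficients = coef, objective = sum(r^2),
         active_set = cs$names[active],
         multipliers = stats::setNames(multipliers, cs$names[active]),
         converged = converged, iterations = iterations,
         kkt_residual = kkt_resid, non_unique = !problem$full_rank,
         method = method, tol = tol),
    class = "cfit_result"
  )
}

#' @export
print.cfit_result <- function(x, ...) {
  cat(sprintf("<cfit_result/%s> objective %.6g, %d iteration(s)%s\n",
              x$method, x$objective, x$iterations,
              if (x$non_unique) ", non-unique (min-norm)" else ""))
  print(x$coefficients)
  if (length(x$active_set))
    cat("  active:", paste(sprintf("%s (lambda=%.3g)", x$active_set,
                                   x$multipliers), collapse = ", "), "\n")
  invisible(x)
}

# A basic feasible point: amplitudes at zero; a free intercept (a column
# not in the non-negativity set) is clamped below the ceiling if needed.
feasible_start <- function(problem, cs) {
  p <- ncol(problem$design)
  x <- rep(0, p)
  free <- setdiff(seq_len(p), problem$nonneg)
  if (!is.null(problem$ceiling)) {
    slack <- problem$y_max - sum(problem$ceiling * x)
    if (slack < 0) {
      j <- free[problem$ceiling[free] > 0][1]
      if (is.na(j) || !length(j))
        stop("infeasible problem: ceiling below zero with all amplitudes at their bound")
      x[j] <- problem$y_max / problem$ceiling[j]
    }
  }
  if (length(cs$h) && any(drop(cs$G %*% x) > cs$h + 1e-9))
    stop("infeasible problem")
  x
}

#' Solve the constrained fit problem by a primal active-set method
#'
#' An exact Karush-Kuhn-Tucker solver for the convex quadratic program of
#' [cfit_problem()]. Starting from a basic feasible point, each iteration
#' minimizes the objective with the current working set of constraints
#' held as equalities; a blocking constraint is added when the step to
#' that minimizer leaves the feasible set, and the constraint with the
#' most negative multiplier is released when the iterate is optimal on
#' its working set. For this convex problem the KKT conditions are
#' necessary and sufficient, so termination yields the global minimizer
#' (the minimum-norm one, flagged `non_unique`, if the design is
#' rank-deficient).
#'
#' @param problem a [cfit_problem()].
#' @param tol feasibility / dual-feasibility tolerance (absolute).
#' @param max_iter iteration cap; exceeding it is an error.
#' @return An object of class `"cfit_result"`: coefficients, objective
#'   (residual sum of squares), active set, KKT multipliers, KKT
#'   stationarity residual, convergence diagnostics.
#' @export
solve_active_set <- function(problem, tol = 1e-9, max_iter = 100L) {
  stopifnot(inherits(problem, "cfit_problem"))
  X <- problem$design
  y <- problem$targets
  cs <- constraint_system(problem)
  m <- length(cs$h)
  XtX2 <- 2 * (crossprod(X) + problem$ridge * diag(ncol(X)))
  Xty2 <- 2 * drop(crossprod(X, y))

  x <- feasible_start(problem, cs)
  W <- integer(0)
  scale <- max(1, max(abs(x)), if (length(y)) max(abs(y)) else 1)
  for (iter in seq_len(max_iter)) {
    E <- cs$G[W, , drop = FALSE]
    d <- cs$h[W]
    sub <- kkt_solve(XtX2, Xty2, E, d)
    step <- sub$z - x
    if (max(abs(step)) <= tol * max(1, max(abs(x)))) {
      lam <- sub$nu
      if (!length(W) || min(lam) >= -tol) {
        # converged: snap active bound constraints exactly
        x <- sub$z
        for (w in W) {
          i <- which(cs$G[w, ] != 0)
          if (length(i) == 1L && cs$h[w] == 0) x[i] <- 0
        }
        return(fit_result(x, problem, cs, W, pmax(lam, 0), TRUE, iter,
                          "active_set", tol))
      }
      W <- W[-which.min(lam)]
    } else {
      Gs <- if (m) drop(cs$G %*% step) else numeric(0)
      slack <- cs$h - if (m) drop(cs$G %*% x) else numeric(0)
      cand <- setdiff(which(Gs > tol * scale), W)
      alpha <- 1
      block <- NA_integer_
      if (length(cand)) {
        ratios <- slack[cand] / Gs[cand]
        k <- which.min(ratios)
        if (ratios[k] < 1) {
          alpha <- max(0, ratios[k])
          block <- cand[k]
        }
      }
      x <- x + alpha * step
      if (!is.na(block)) W <- c(W, block)
    }
  }
  stop(sprintf(
    "active-set solver did not converge in %d iterations (last objective %.6g)",
    max_iter, sum((drop(X %*% x) - y)^2)))
}

#' Exhaustive active-set oracle
#'
#' Verification oracle for [solve_active_set()]: enumerates every subset
#' of the inequality constraints as a candidate active set, solves each
#' equality-constrained least-squares problem through its KKT linear
#' system, discards primal-infeasible candidates, and returns the
#' feasible candidate with the smallest objective. Exact but exponential
#' in the number of constraints, hence capped; intended for testing the
#' main solver, not for production fits.
#'
#' @param problem a [cfit_problem()] with at most `max_constraints`
#'   inequality constraints.
#' @param tol feasibility tolerance.
#' @param max_constraints enumeration cap (default 12).
#' @return A `"cfit_result"`, as for [solve_active_set()].
#' @export
solve_oracle <- function(problem, tol = 1e-9, max_constraints = 12L) {
  stopifnot(inherits(problem, "cfit_problem"))
  cs <- constraint_system(problem)
  m <- length(cs$h)
  if (m > max_constraints)
    stop("too many constraints for exhaustive enumeration; use solve_active_set()")
  X <- problem$design
  y <- problem$targets
  XtX2 <- 2 * (crossprod(X) + problem$ridge * diag(ncol(X)))
  Xty2 <- 2 * drop(crossprod(X, y))
  scale <- max(1, max(abs(y)), max(abs(cs$h[is.finite(cs$h)]), 0))

  best <- NULL
  n_cand <- 0L
  for (mask in 0:(2^m - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    sub <- kkt_solve(XtX2, Xty2, cs$G[S, , drop = FALSE], cs$h[S])
    if (!sub$consistent) next
    z <- sub$z
    if (m && any(drop(cs$G %*% z) > cs$h + tol * scale)) next
    n_cand <- n_cand + 1L
    # candidates are ranked by the (ridged) objective actually minimized
    obj <- sum((drop(X %*% z) - y)^2) + problem$ridge * sum(z^2)
    if (is.null(best) || obj < best$obj - 1e-12 * max(1, best$obj) ||
        (abs(obj - best$obj) <= 1e-12 * max(1, best$obj) &&
         length(S) < length(best$S))) {
      best <- list(z = z, nu = sub$nu, S = S, obj = obj)
    }
  }
  if (is.null(best))
    stop("infeasible problem")
  fit_result(best$z, problem, cs, best$S, pmax(best$nu, 0), TRUE, n_cand,
             "oracle", tol)
}
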