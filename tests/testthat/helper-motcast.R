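# Shared builders for the test suite. All randomness is seeded by the
# caller.

# A small cohort whose trajectories are exact affine copies of one
# saturating curve: y_J(t) = alpha_J + beta_J * g(t), beta_J > 0.
affine_copy_cohort <- function(n_patients = 5,
                               ages = seq(15, 105, by = 15),
                               alphas = NULL, betas = NULL) {
  g <- 1 - exp(-0.05 * ages)
  if (is.null(alphas)) alphas <- seq(2, 10, length.out = n_patients)
  if (is.null(betas)) betas <- seq(20, 40, length.out = n_patients)
  obs <- do.call(rbind, lapply(seq_len(n_patients), function(j)
    data.frame(patient_id = paste0("p", j), age_months = ages,
               value = alphas[j] + betas[j] * g)))
  cohort(obs)
}

# A random valid monotone trend model.
random_monotone_model <- function() {
  q <- sample(0:3, 1)
  exp_trend(runif(1, -30, 30),
            if (q) runif(q, 0, 40) else numeric(),
            if (q) sort(exp(runif(q, log(1e-3), log(0.5)))) else numeric(),
            monotone = TRUE)
}

# A random constrained fit problem from the geometry the package builds:
# either a saturating-exponential design with separated rates (plus
# intercept, amplitude non-negativity, ceiling at a horizon) or a dense
# random design with random non-negativity set and ceiling. Includes
# rank-boundary cases (fewer observations than parameters).
random_cfit_problem <- function() {
  n <- sample(1:8, 1)
  if (runif(1) < 0.6) {
    q <- sample(1:3, 1)
    repeat {
      rates <- sort(exp(runif(q, log(1e-3), log(0.5))))
      if (q == 1 || all(rates[-1] / rates[-q] >= 1.2)) break
    }
    tg <- sort(sample(seq(3, 120, by = 3), n))
    design <- cbind(1, 1 - exp(-outer(tg, rates)))
    nonneg <- seq_len(q) + 1L
    ceil <- c(1, 1 - exp(-rates * 130))
    y <- runif(1, -10, 30) + stats::rnorm(n, 0, 5)
  } else {
    p <- sample(1:4, 1)
    design <- matrix(stats::rnorm(n * p), n, p)
    nonneg <- sample(seq_len(p), sample(1:p, 1))
    ceil <- abs(stats::rnorm(p))
    y <- stats::rnorm(n, 0, 5)
  }
  y_max <- if (runif(1) < 0.3) Inf else runif(1, 0.1, 40)
  cfit_problem(design, y, nonneg = nonneg, ceiling = ceil, y_max = y_max)
}

tmp_path <- function(ext) tempfile(fileext = ext)
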