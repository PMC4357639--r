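#' Population parameter values of the simulation design
#'
#' The generating values used throughout the Monte-Carlo studies: the
#' maximum-likelihood estimates from the motivating posttraumatic-stress
#' example, rounded to four decimals.
#'
#' @return A [parameter_set] with `mu_I = 54.0900`, `mu_LS = -12.4810`,
#'   `mu_QS = 1.7590`, `beta = 10.0080`, `var_I = 593.6330`,
#'   `var_LS = 199.3820`, `var_QS = 134.6140`.
#' @export
default_population <- function() {
  parameter_set(mu_I = 54.0900, mu_LS = -12.4810, mu_QS = 1.7590,
                beta = 10.0080,
                var_I = 593.6330, var_LS = 199.3820, var_QS = 134.6140)
}

#' Simulation design: population, sample size, allocation, replications
#'
#' @param population A [parameter_set] of generating values.
#' @param n Subjects per dataset (>= 2).
#' @param group_allocation Proportion assigned to group 1, strictly between 0
#'   and 1.  Group counts are deterministic: exactly `round(n *
#'   group_allocation)` subjects get group 1, so no replicate can degenerate
#'   to a single group at small n.
#' @param n_reps Number of replicate datasets (>= 1).
#' @param seed Root seed; each replicate draws from an independent
#'   reproducible stream derived from `(seed, replicate_index)`.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(population = default_population(), n = 8,
                              group_allocation = 0.5, n_reps = 1000, seed = 1) {
  if (!inherits(population, "parameter_set")) {
    input_error("`population` must be a parameter_set")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2) input_error("`n` must be >= 2")
  if (!is.numeric(group_allocation) || group_allocation <= 0 || group_allocation >= 1) {
    input_error("`group_allocation` must be strictly between 0 and 1")
  }
  if (!is.numeric(n_reps) || n_reps < 1) input_error("`n_reps` must be >= 1")
  n1 <- round(n * group_allocation)
  if (n1 < 1 || n1 > n - 1) {
    input_error("group allocation leaves a group empty at this sample size")
  }
  structure(list(population = population, n = as.integer(n),
                 group_allocation = group_allocation,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "simulation_design")
}

design_group <- function(design) {
  n1 <- round(design$n * design$group_allocation)
  c(rep(0L, design$n - n1), rep(1L, n1))
}

#' Generate one replicate dataset from a simulation design
#'
#' Draws the three growth factors independently per subject,
#' `I ~ N(mu_I, var_I)`, `LS ~ N(mu_LS + beta * group, var_LS)`,
#' `QS ~ N(mu_QS, var_QS)`, and maps them to occasion scores through the
#' fixed loadings.  The RNG stream is fully determined by
#' `(design$seed, replicate_index)` so any replicate can be regenerated in
#' isolation.
#'
#' @param design A [simulation_design].
#' @param replicate_index Positive integer identifying the replicate.
#' @param basis A [build_contrast_basis()] object.
#' @return A [longitudinal_data] object with attributes `replicate_index` and
#'   `scores` (the generating factor scores).
#' @export
generate_dataset <- function(design, replicate_index = 1L,
                             basis = build_contrast_basis()) {
  if (!inherits(design, "simulation_design")) {
    input_error("`design` must be a simulation_design")
  }
  if (!is.numeric(replicate_index) || replicate_index < 1) {
    input_error("`replicate_index` must be a positive integer")
  }
  p <- design$population
  g <- design_group(design)
  n <- design$n
  eta <- with_seed(derive_seed(design$seed, replicate_index), {
    cbind(I  = stats::rnorm(n, p$mu_I, sqrt(p$var_I)),
          LS = stats::rnorm(n, p$mu_LS + p$beta * g, sqrt(p$var_LS)),
          QS = stats::rnorm(n, p$mu_QS, sqrt(p$var_QS)))
  })
  y <- eta %*% basis$contrast_matrix  # y' = Lambda eta  <=>  Y = H C (Lambda = C')
  out <- longitudinal_data(y, g)
  attr(out, "replicate_index") <- as.integer(replicate_index)
  attr(out, "scores") <- eta
  out
}

#' Synthetic stand-in for the empirical burn-survivor dataset
#'
#' The motivating clinical data are not deposited.  For demonstrations (the
#' prior-sensitivity grid in particular) this generates a synthetic dataset
#' of the empirical study's size and group split and then rescales the growth
#' scores so that the maximum-likelihood fit reproduces the published
#' estimates exactly by construction (intercept mean 54.090, slope mean
#' -12.481, group coefficient 10.008, and the simulation-design variances).
#' It is a calibrated synthetic stand-in, not the clinical data.
#'
#' @param n Total sample size (default 78 as in the empirical study).
#' @param n_exposed Number of group-1 subjects (default 15, the ventilated
#'   count).
#' @param seed RNG seed.
#' @param targets [parameter_set] the ML fit is calibrated to.
#' @return A [longitudinal_data] object.
#' @export
demo_dataset <- function(n = 78, n_exposed = 15, seed = 20150311,
                         targets = default_population()) {
  if (n_exposed < 1 || n_exposed > n - 1) input_error("both groups must be non-empty")
  design <- simulation_design(targets, n = n, group_allocation = n_exposed / n,
                              n_reps = 1, seed = seed)
  basis <- build_contrast_basis()
  d <- generate_dataset(design, 1L, basis)
  eta <- transform_to_growth_scores(d, basis)
  g <- d$group
  # Rescale each factor-score set so the ML estimates hit the targets exactly:
  # centre/scale with the ML (divide-by-n) variance, then place at the target.
  ml_scale <- function(x, mu, v) {
    e <- x - mean(x)
    s <- sqrt(mean(e^2))
    mu + e / s * sqrt(v)
  }
  I <- ml_scale(eta[, "I"], targets$mu_I, targets$var_I)
  QS <- ml_scale(eta[, "QS"], targets$mu_QS, targets$var_QS)
  X <- cbind(1, g)
  b <- solve(crossprod(X), crossprod(X, eta[, "LS"]))
  e <- eta[, "LS"] - X %*% b          # orthogonal to X, so recalibration is exact
  e <- e / sqrt(mean(e^2)) * sqrt(targets$var_LS)
  LS <- targets$mu_LS + targets$beta * g + drop(e)
  longitudinal_data(cbind(I, LS, QS) %*% basis$contrast_matrix, g)
}
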