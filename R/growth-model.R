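#' Orthonormal polynomial contrast basis for three equally spaced occasions
#'
#' A repeated-measures ANOVA on three occasions can be written as a latent
#' growth model whose intercept, linear-slope and quadratic-slope factors have
#' fixed loadings.  The loadings are the transpose of the orthonormal
#' polynomial contrast matrix over occasion levels 1, 2, 3:
#' intercept \eqn{(1,1,1)/\sqrt{3}}, linear \eqn{(-1,0,1)/\sqrt{2}},
#' quadratic \eqn{(1,-2,1)/\sqrt{6}}.  Because the rows are orthonormal the
#' loading matrix is simply the transpose of the contrast matrix and the two
#' are exact inverses: contrast scores are a lossless linear recoding of the
#' observed occasion vector.
#'
#' @return An object of class `contrast_basis`: a list with
#'   `contrast_matrix` (3x3, rows I/LS/QS) and `loading_matrix` (its
#'   transpose).
#' @examples
#' b <- build_contrast_basis()
#' b$contrast_matrix %*% b$loading_matrix  # identity
#' @export
build_contrast_basis <- function() {
  C <- rbind(
    I  = c(1, 1, 1) / sqrt(3),
    LS = c(-1, 0, 1) / sqrt(2),
    QS = c(1, -2, 1) / sqrt(6)
  )
  colnames(C) <- c("y1", "y2", "y3")
  structure(list(contrast_matrix = C, loading_matrix = t(C)),
            class = "contrast_basis")
}

parameter_names <- function() {
  c("mu_I", "mu_LS", "mu_QS", "beta", "var_I", "var_LS", "var_QS")
}

#' Model parameters of the three-occasion growth model
#'
#' Bundles the seven parameters: the three factor means (intercept `mu_I`,
#' linear slope `mu_LS` for the reference group, quadratic slope `mu_QS`),
#' the group difference `beta` in the linear-slope mean (group 1 minus
#' group 0), and the three factor variances.  Factor covariances are fixed to
#' zero and the occasion residual variances are fixed to zero, so these seven
#' numbers fully determine the observed-data distribution.
#'
#' @param mu_I,mu_LS,mu_QS Factor means (contrast-score units of the outcome).
#' @param beta Group difference in the linear-slope mean.
#' @param var_I,var_LS,var_QS Non-negative factor variances (`var_LS` is the
#'   residual variance of the linear slope after the group regression).
#' @return An object of class `parameter_set` (named list).
#' @export
parameter_set <- function(mu_I, mu_LS, mu_QS, beta, var_I, var_LS, var_QS) {
  p <- list(mu_I = mu_I, mu_LS = mu_LS, mu_QS = mu_QS, beta = beta,
            var_I = var_I, var_LS = var_LS, var_QS = var_QS)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      input_error(sprintf("parameter `%s` must be a single finite number", nm))
    }
  }
  for (nm in c("var_I", "var_LS", "var_QS")) {
    if (p[[nm]] < 0) input_error(sprintf("variance `%s` must be non-negative", nm))
  }
  structure(p, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Growth-model parameters:\n")
  print(unlist(x[parameter_names()]))
  invisible(x)
}

#' Three-occasion repeated-measures dataset with a binary group indicator
#'
#' @param outcomes n x 3 numeric matrix of the repeated outcome, columns in
#'   assessment order (first, second, third).  No missing values
#'   (complete-case design).
#' @param group Length-n vector of 0/1 (1 = exposed group).
#' @return An object of class `longitudinal_data`.
#' @export
longitudinal_data <- function(outcomes, group) {
  outcomes <- as.matrix(outcomes)
  if (!is.numeric(outcomes) || ncol(outcomes) != 3L) {
    input_error("`outcomes` must be a numeric matrix with 3 columns")
  }
  if (anyNA(outcomes) || any(!is.finite(outcomes))) {
    input_error("`outcomes` must be complete (no missing or non-finite values)")
  }
  group <- as.vector(group)
  if (length(group) != nrow(outcomes)) {
    input_error("`group` must have one entry per subject")
  }
  if (anyNA(group) || !all(group %in% c(0, 1))) {
    input_error("`group` must contain only 0 and 1")
  }
  colnames(outcomes) <- c("y1", "y2", "y3")
  structure(list(outcomes = outcomes, group = as.integer(group)),
            class = "longitudinal_data")
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat(sprintf("Longitudinal dataset: n=%d subjects x 3 occasions (%d in group 1)\n",
              nrow(x$outcomes), sum(x$group)))
  invisible(x)
}

#' Per-subject growth (contrast) scores
#'
#' Applies the contrast matrix to each subject's occasion vector, yielding the
#' intercept, linear-slope and quadratic-slope scores \eqn{\eta = C y}.  With
#' occasion residual variances fixed at zero this transform is exact and
#' invertible: `scores %*% t(loading_matrix)` reconstructs the outcomes.
#'
#' @param data A [longitudinal_data] object.
#' @param basis A [build_contrast_basis()] object.
#' @return n x 3 matrix with columns `I`, `LS`, `QS` and the group vector
#'   attached as attribute `group`.
#' @export
transform_to_growth_scores <- function(data, basis = build_contrast_basis()) {
  if (!inherits(data, "longitudinal_data")) {
    input_error("`data` must be a longitudinal_data object")
  }
  C <- basis$contrast_matrix
  if (ncol(data$outcomes) != ncol(C)) input_error("dimension mismatch between data and basis")
  scores <- data$outcomes %*% t(C)
  colnames(scores) <- rownames(C)
  attr(scores, "group") <- data$group
  scores
}

#' Implied observed-data moments of the growth model
#'
#' The mean and covariance of the three occasion scores implied by a
#' parameter set for one group: mean \eqn{\Lambda (\mu_I, \mu_{LS} + \beta g,
#' \mu_{QS})'} and covariance \eqn{\Lambda \mathrm{diag}(\sigma^2_I,
#' \sigma^2_{LS}, \sigma^2_{QS}) \Lambda'} (factor covariances and occasion
#' residual variances are fixed at zero).
#'
#' @param params A [parameter_set].
#' @param basis A [build_contrast_basis()] object.
#' @param group_value 0 or 1.
#' @return List with `mean` (length 3) and `covariance` (3x3).
#' @export
implied_moments <- function(params, basis = build_contrast_basis(), group_value = 0) {
  if (!inherits(params, "parameter_set")) {
    params <- do.call(parameter_set, as.list(unclass(params))[parameter_names()])
  }
  if (!group_value %in% c(0, 1)) input_error("`group_value` must be 0 or 1")
  L <- basis$loading_matrix
  eta_mean <- c(params$mu_I, params$mu_LS + params$beta * group_value, params$mu_QS)
  D <- diag(c(params$var_I, params$var_LS, params$var_QS), nrow = 3)
  list(mean = drop(L %*% eta_mean), covariance = L %*% D %*% t(L))
}
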