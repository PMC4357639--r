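#' Normal prior for a structural parameter
#'
#' @param mean Prior mean (mu0).
#' @param variance Prior variance (sigma0^2), strictly positive.  Large
#'   values (the default elsewhere is 1e10) make the prior effectively flat;
#'   small values make it informative and pull the posterior toward `mean`.
#' @return Object of class `c("normal_prior", "bayesrma_prior")`.
#' @export
normal_prior <- function(mean = 0, variance = 1e10) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    input_error("normal prior `mean` must be a single finite number")
  }
  if (!is.numeric(variance) || length(variance) != 1L || !(variance > 0)) {
    input_error("normal prior `variance` must be > 0")
  }
  structure(list(mean = mean, variance = variance),
            class = c("normal_prior", "bayesrma_prior"))
}

#' Inverse-gamma prior for a variance parameter
#'
#' Parameterized with density proportional to
#' \eqn{x^{-shape-1} \exp(-scale/x)}.  `IG(-1, 0)` is the flat-but-positive
#' improper default of SEM software; `IG(0.5, 0.5)` is a proper, informative
#' choice.  Improper settings are accepted here because propriety of the
#' *conditional* posterior (shape + n/2 > 0) is what the sampler requires and
#' it checks that at fit time.
#'
#' @param shape,scale Hyperparameters; `scale` must be non-negative.
#' @return Object of class `c("inv_gamma_prior", "bayesrma_prior")`.
#' @export
inv_gamma_prior <- function(shape, scale) {
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape)) {
    input_error("inverse-gamma `shape` must be a single finite number")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !(scale >= 0)) {
    input_error("inverse-gamma `scale` must be >= 0")
  }
  structure(list(shape = shape, scale = scale),
            class = c("inv_gamma_prior", "bayesrma_prior"))
}

#' Is a prior a proper probability distribution?
#'
#' An inverse-gamma prior is proper iff both shape and scale are strictly
#' positive; a normal prior with finite positive variance is always proper.
#'
#' @param prior A prior object.
#' @return Logical.
#' @export
is_proper <- function(prior) UseMethod("is_proper")

#' @export
is_proper.normal_prior <- function(prior) TRUE

#' @export
is_proper.inv_gamma_prior <- function(prior) prior$shape > 0 && prior$scale > 0

structural_names <- function() c("mu_I", "mu_LS", "beta", "mu_QS")
variance_names <- function() c("var_I", "var_LS", "var_QS")

#' Per-parameter prior specification
#'
#' @param structural Named list of [normal_prior]s for `mu_I`, `mu_LS`,
#'   `beta`, `mu_QS`.
#' @param variances Named list of [inv_gamma_prior]s for `var_I`, `var_LS`,
#'   `var_QS`.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(structural, variances) {
  if (!setequal(names(structural), structural_names())) {
    input_error("`structural` must supply priors for mu_I, mu_LS, beta, mu_QS")
  }
  if (!setequal(names(variances), variance_names())) {
    input_error("`variances` must supply priors for var_I, var_LS, var_QS")
  }
  for (nm in structural_names()) {
    if (!inherits(structural[[nm]], "normal_prior")) {
      input_error(sprintf("structural prior `%s` must be a normal_prior", nm))
    }
  }
  for (nm in variance_names()) {
    if (!inherits(variances[[nm]], "inv_gamma_prior")) {
      input_error(sprintf("variance prior `%s` must be an inv_gamma_prior", nm))
    }
  }
  structure(list(structural = structural[structural_names()],
                 variances = variances[variance_names()]),
            class = "prior_spec")
}

#' Default (diffuse) prior settings
#'
#' Normal(0, 1e10) for the four structural parameters — effectively flat —
#' and the improper flat-but-positive inverse-gamma IG(-1, 0) for the three
#' variances, mirroring the defaults of mainstream Bayesian SEM software.
#'
#' @return A [prior_spec].
#' @export
default_priors <- function() {
  s <- lapply(structural_names(), function(nm) normal_prior(0, 1e10))
  names(s) <- structural_names()
  v <- lapply(variance_names(), function(nm) inv_gamma_prior(-1, 0))
  names(v) <- variance_names()
  prior_spec(s, v)
}

#' Replace selected priors in a specification
#'
#' Convenience for sensitivity grids: returns `priors` with the named
#' entries replaced.
#'
#' @param priors A [prior_spec].
#' @param ... Named priors, e.g. `beta = normal_prior(10, 50)` or
#'   `var_I = inv_gamma_prior(0.5, 0.5)`.
#' @return A [prior_spec].
#' @export
set_prior <- function(priors, ...) {
  repl <- list(...)
  s <- priors$structural
  v <- priors$variances
  for (nm in names(repl)) {
    if (nm %in% structural_names()) s[[nm]] <- repl[[nm]]
    else if (nm %in% variance_names()) v[[nm]] <- repl[[nm]]
    else input_error(sprintf("unknown parameter `%s`", nm))
  }
  prior_spec(s, v)
}
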