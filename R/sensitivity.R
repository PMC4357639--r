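#' Prior-sensitivity grid for the group coefficient
#'
#' Refits the model by Gibbs sampling for every combination of prior mean
#' `mu0` and prior variance `var0` assigned to `beta`, holding the data, the
#' other priors and the seed fixed so that differences between cells reflect
#' the prior alone.  Each cell records the posterior point estimate (mu1),
#' posterior SD (sigma1), the 95% posterior probability interval and the
#' significance flag.
#'
#' The expected qualitative behaviour, useful for reading the output: the
#' posterior SD shrinks as `var0` shrinks; the point estimate is a
#' precision-weighted compromise between `mu0` and the data estimate, so a
#' badly misspecified `mu0` with a small `var0` can produce a significant
#' effect in the opposite direction from the ML fit.
#'
#' @param data A [longitudinal_data] object.
#' @param mu0_grid Prior means to try (the demonstration grid is
#'   `c(5, 0, -5, -10)`).
#' @param var0_grid Prior variances to try (the demonstration grid is
#'   `c(1e10, 1000, 100, 50, 20, 10, 5, 3, 1)`).
#' @param base_priors Priors for all non-`beta` parameters (default
#'   [default_priors()]).
#' @param config A [sampler_config]; its seed is reused for every cell.
#' @param basis A [build_contrast_basis()] object.
#' @return Data frame of class `sensitivity_grid` with one row per cell:
#'   `mu0`, `var0`, `posterior_point`, `posterior_sd`, `lower`, `upper`,
#'   `significant`, `error` (NA unless the cell failed).
#' @export
run_prior_grid <- function(data,
                           mu0_grid = c(5, 0, -5, -10),
                           var0_grid = c(1e10, 1000, 100, 50, 20, 10, 5, 3, 1),
                           base_priors = default_priors(),
                           config = sampler_config(),
                           basis = build_contrast_basis()) {
  if (length(mu0_grid) == 0 || length(var0_grid) == 0) {
    input_error("grids must be non-empty")
  }
  cells <- expand.grid(mu0 = mu0_grid, var0 = var0_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    mu0 <- cells$mu0[i]; var0 <- cells$var0[i]
    res <- tryCatch({
      pr <- set_prior(base_priors, beta = normal_prior(mu0, var0))
      ch <- gibbs_sample(data, basis, pr, config)
      s <- summarize_posterior(ch, config)
      b <- s[s$parameter == "beta", ]
      data.frame(mu0 = mu0, var0 = var0, posterior_point = b$point,
                 posterior_sd = b$posterior_sd, lower = b$lower,
                 upper = b$upper, significant = b$significant,
                 error = NA_character_)
    }, bayesrma_error = function(e) {
      data.frame(mu0 = mu0, var0 = var0, posterior_point = NA_real_,
                 posterior_sd = NA_real_, lower = NA_real_, upper = NA_real_,
                 significant = NA, error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_grid", "data.frame")
  out
}

#' Line plot of a sensitivity grid
#'
#' Posterior point estimate (or SD) of `beta` against the prior variance,
#' one line per prior mean, on a log-scaled x axis.
#'
#' @param x A `sensitivity_grid`.
#' @param what `"point"` or `"sd"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sensitivity_grid <- function(x, what = c("point", "sd"), ...) {
  what <- match.arg(what)
  col <- if (what == "point") "posterior_point" else "posterior_sd"
  wide <- stats::reshape(as.data.frame(x)[, c("mu0", "var0", col)],
                         idvar = "var0", timevar = "mu0", direction = "wide")
  wide <- wide[order(wide$var0), ]
  graphics::matplot(wide$var0, wide[, -1], type = "b", log = "x", pch = 16,
                    xlab = "prior variance of beta",
                    ylab = if (what == "point") "posterior point (mu1)" else "posterior SD (sigma1)",
                    ...)
  graphics::legend("topleft", legend = sub("^[a-z_]+\\.", "mu0=", names(wide)[-1]),
                   col = seq_len(ncol(wide) - 1), lty = seq_len(ncol(wide) - 1),
                   bty = "n")
  invisible(x)
}
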