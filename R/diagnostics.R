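#' Spike report for a single-parameter chain
#'
#' Improper or near-improper inverse-gamma variance priors at very small n
#' produce occasional draws orders of magnitude above the bulk of the chain
#' — visible as spikes in the trace plot and the source of grossly inflated
#' variance estimates.  A "spike" is operationalized scale-free as a draw
#' exceeding `threshold_multiplier` times the chain median (default 50).
#'
#' @param chain Non-empty numeric vector of draws from a positive-valued
#'   parameter (the chain median must be positive).
#' @param threshold_multiplier Multiplier (> 1) applied to the chain median.
#' @param parameter Optional parameter name for the report.
#' @return Object of class `spike_report`: list with `parameter`,
#'   `n_spikes`, `spike_iterations`, `max_draw`, `median_draw`,
#'   `threshold_used`.
#' @export
spike_report <- function(chain, threshold_multiplier = 50, parameter = "parameter") {
  if (length(chain) == 0) input_error("`chain` must be non-empty")
  if (!is.numeric(threshold_multiplier) || threshold_multiplier <= 1) {
    input_error("`threshold_multiplier` must be > 1")
  }
  med <- stats::median(chain)
  if (!(med > 0)) {
    input_error("spike detection is defined for positive-valued chains (median > 0)")
  }
  threshold <- threshold_multiplier * med
  idx <- which(chain > threshold)
  structure(list(parameter = parameter, n_spikes = length(idx),
                 spike_iterations = idx, max_draw = max(chain),
                 median_draw = med, threshold_used = threshold),
            class = "spike_report")
}

#' @export
print.spike_report <- function(x, ...) {
  cat(sprintf("Spike report for %s: %d spike(s) above %.4g (median %.4g, max %.4g)\n",
              x$parameter, x$n_spikes, x$threshold_used, x$median_draw, x$max_draw))
  invisible(x)
}

#' Split-half potential scale reduction factor
#'
#' Convergence check on a single retained chain: the chain is split into two
#' halves treated as parallel chains and the usual between/within variance
#' ratio is computed, square-rooted.  Values near 1 indicate the two halves
#' agree in mean and variance; values well above 1.1 flag nonstationarity.
#'
#' @param chain Numeric vector, length >= 4, non-constant.
#' @return The split-half PSRF.
#' @export
split_psrf <- function(chain) {
  if (length(chain) < 4) input_error("`chain` must have at least 4 draws")
  L <- floor(length(chain) / 2)
  h1 <- chain[seq_len(L)]
  h2 <- chain[seq.int(length(chain) - L + 1, length(chain))]
  W <- (stats::var(h1) + stats::var(h2)) / 2
  if (!is.finite(W) || W <= 0) {
    input_error("degenerate chain: zero within-half variance")
  }
  B <- L * stats::var(c(mean(h1), mean(h2)))
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Iteration-stability check of the posterior point estimate
#'
#' Refits the model with increasing iteration counts and reports the percent
#' change in the `beta` point estimate relative to the first count — the
#' scripted version of the convergence check of doubling (or quintupling)
#' the chain length and confirming the estimate moves by a fraction of a
#' percent.
#'
#' @param data A [longitudinal_data] object.
#' @param priors A [prior_spec].
#' @param config A [sampler_config]; its `n_iterations` is overridden by the
#'   grid.
#' @param n_iterations_grid Iteration counts to compare (default
#'   `c(10000, 50000)`).
#' @param basis A [build_contrast_basis()] object.
#' @return Data frame with `n_iterations`, `beta_point`,
#'   `pct_change_vs_first`.
#' @export
iteration_doubling_check <- function(data, priors = default_priors(),
                                     config = sampler_config(),
                                     n_iterations_grid = c(10000, 50000),
                                     basis = build_contrast_basis()) {
  pts <- vapply(n_iterations_grid, function(ni) {
    cfg <- sampler_config(n_iterations = ni,
                          burn_in_fraction = config$burn_in_fraction,
                          seed = config$seed,
                          point_estimate_rule = config$point_estimate_rule)
    s <- summarize_posterior(gibbs_sample(data, basis, priors, cfg), cfg)
    s$point[s$parameter == "beta"]
  }, numeric(1))
  data.frame(n_iterations = n_iterations_grid, beta_point = pts,
             pct_change_vs_first = (pts / pts[1] - 1) * 100)
}
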