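# Shared fixtures and independent oracles for the test suite.

# Prior spec with all three variance priors set to IG(shape, scale) and flat
# normal structural priors.
ig_priors <- function(shape, scale) {
  p <- default_priors()
  for (nm in c("var_I", "var_LS", "var_QS")) {
    p$variances[[nm]] <- inv_gamma_prior(shape, scale)
  }
  p
}

# Inverse-gamma CDF (density prop. to x^{-shape-1} exp(-scale/x)).
pinvgamma <- function(q, shape, scale) {
  stats::pgamma(1 / q, shape = shape, rate = scale, lower.tail = FALSE)
}

# Multivariate-normal log-likelihood of a data matrix, via Cholesky.
# Independent of the package's fitting code.
mvn_loglik <- function(Y, mean, cov) {
  L <- chol(cov)
  z <- forwardsolve(t(L), t(Y) - mean)
  -0.5 * ncol(Y) * log(2 * pi) * nrow(Y) - nrow(Y) * sum(log(diag(L))) -
    0.5 * sum(z^2)
}

# Brute-force numerical maximizer of the growth-model likelihood built from
# implied_moments(); the independent oracle for the closed-form ML fit.
# Parameters: 4 structural + 3 log-variances.
numeric_ml_oracle <- function(data, basis = build_contrast_basis()) {
  nll <- function(th) {
    p <- tryCatch(
      parameter_set(mu_I = th[1], mu_LS = th[2], mu_QS = th[3], beta = th[4],
                    var_I = exp(th[5]), var_LS = exp(th[6]), var_QS = exp(th[7])),
      error = function(e) NULL)
    if (is.null(p)) return(1e10)
    total <- 0
    for (g in 0:1) {
      rows <- data$outcomes[data$group == g, , drop = FALSE]
      if (nrow(rows) == 0) next
      m <- implied_moments(p, basis, g)
      total <- total + mvn_loglik(rows, m$mean, m$covariance)
    }
    -total
  }
  # Generic moment-based starting values (not the closed form under test).
  ybar <- mean(data$outcomes)
  v0 <- log(stats::var(as.vector(data$outcomes)) + 1)
  th0 <- c(sqrt(3) * ybar, 0, 0, 0, v0, v0, v0)
  fit <- stats::optim(th0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  c(mu_I = fit$par[1], mu_LS = fit$par[2], mu_QS = fit$par[3],
    beta = fit$par[4], var_I = exp(fit$par[5]), var_LS = exp(fit$par[6]),
    var_QS = exp(fit$par[7]))
}

# Dense-grid integration oracle for the posterior of (mu_LS, beta) under
# flat-ish normal priors and an inverse-gamma prior on var_LS.  Integrates
# the unnormalized joint over a 3-D grid and returns the marginal posterior
# mean and SD of beta.
grid_beta_oracle <- function(data, ig_shape, ig_scale,
                             n_mu = 61, n_beta = 61, n_var = 81) {
  eta <- transform_to_growth_scores(data)
  y <- eta[, "LS"]; g <- data$group; n <- length(y)
  X <- cbind(1, g)
  b <- solve(crossprod(X), crossprod(X, y))
  se_scale <- sqrt(sum((y - X %*% b)^2) / max(n - 2, 1))
  mu_grid <- seq(b[1] - 8 * se_scale, b[1] + 8 * se_scale, length.out = n_mu)
  beta_grid <- seq(b[2] - 10 * se_scale, b[2] + 10 * se_scale, length.out = n_beta)
  v_grid <- exp(seq(log(se_scale^2 / 50), log(se_scale^2 * 50), length.out = n_var))
  sy <- sum(y); syg <- sum(y * g); ssy <- sum(y^2); n1 <- sum(g)
  grid <- expand.grid(mu = mu_grid, beta = beta_grid, v = v_grid)
  SS <- ssy - 2 * grid$mu * sy - 2 * grid$beta * syg +
    n * grid$mu^2 + 2 * grid$mu * grid$beta * n1 + grid$beta^2 * n1
  logw <- -n / 2 * log(grid$v) - SS / (2 * grid$v) +
    (-ig_shape - 1) * log(grid$v) - ig_scale / grid$v +
    log(grid$v)  # Jacobian of the log-spaced v grid
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  m <- sum(w * grid$beta)
  list(mean = m, sd = sqrt(sum(w * (grid$beta - m)^2)))
}

# Score matrices for R replicates of a design, for use with the internal
# vectorized engine.
replicate_scores <- function(design) {
  n <- design$n
  R <- design$n_reps
  I <- LS <- QS <- matrix(NA_real_, n, R)
  for (r in seq_len(R)) {
    eta <- transform_to_growth_scores(generate_dataset(design, r))
    I[, r] <- eta[, "I"]; LS[, r] <- eta[, "LS"]; QS[, r] <- eta[, "QS"]
  }
  list(I = I, LS = LS, QS = QS, group = bayesrma:::design_group(design))
}
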