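test_that("wald_interval matches hand arithmetic and handles edge cases", {
  expect_equal(wald_interval(0, 1, 0.95), c(lower = -1.96, upper = 1.96),
               tolerance = 1e-3)
  # arithmetic on the published group-coefficient estimate and SE
  ci <- wald_interval(10.008, 4.057, 0.95)
  expect_equal(round(unname(ci), 3), c(2.056, 17.960))
  expect_equal(wald_interval(5, 0, 0.95), c(lower = 5, upper = 5))
  expect_error(wald_interval(0, 1, 1.2), class = "bayesrma_input_error")
  expect_error(wald_interval(0, -1, 0.95), class = "bayesrma_input_error")
})

test_that("degenerate within-group profiles give exact means, zero variances", {
  b <- build_contrast_basis()
  # one shared profile per group, differing only along the linear contrast
  # (the single direction the group indicator is allowed to shift)
  y0 <- c(40, 28, 25)
  y1 <- y0 + 7 * c(-1, 0, 1) / sqrt(2)
  y <- rbind(y0, y0, y0, y1, y1, y1)
  d <- longitudinal_data(y, c(0, 0, 0, 1, 1, 1))
  fit <- fit_ml(d)
  eta0 <- drop(b$contrast_matrix %*% y0)
  eta1 <- drop(b$contrast_matrix %*% y1)
  expect_equal(fit$estimates$mu_I, mean(c(rep(eta0[1], 3), rep(eta1[1], 3))))
  expect_equal(fit$estimates$mu_LS, unname(eta0[2]))
  expect_equal(fit$estimates$beta, unname(eta1[2] - eta0[2]))
  expect_equal(fit$estimates$beta, 7)
  expect_equal(fit$estimates$var_I, 0)
  expect_equal(fit$estimates$var_LS, 0)
  expect_equal(fit$estimates$var_QS, 0)
  expect_true(all(c("var_I", "var_LS", "var_QS") %in% fit$truncated_variances))
})

test_that("ML is consistent: large-sample beta near the population value", {
  d <- generate_dataset(simulation_design(n = 100000, seed = 77), 1)
  fit <- fit_ml(d)
  expect_lt(abs(fit$estimates$beta - 10.008),
            3 * fit$standard_errors[["beta"]])
})

test_that("closed form agrees with a numerical likelihood maximizer", {
  des <- simulation_design(n = 8, n_reps = 50, seed = 314)
  worst <- 0
  for (r in seq_len(50)) {
    d <- generate_dataset(des, r)
    closed <- unlist(fit_ml(d)$estimates[bayesrma:::parameter_names()])
    oracle <- numeric_ml_oracle(d)
    rel <- abs(oracle - closed) / pmax(abs(closed), 1e-4)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 1e-4)
})

test_that("fit is equivariant to relabeling the groups", {
  d <- generate_dataset(simulation_design(n = 14, seed = 6), 1)
  f1 <- fit_ml(d)
  f2 <- fit_ml(longitudinal_data(d$outcomes, 1 - d$group))
  expect_equal(f2$estimates$beta, -f1$estimates$beta)
  expect_equal(f2$estimates$mu_LS, f1$estimates$mu_LS + f1$estimates$beta)
  expect_equal(f2$estimates$var_LS, f1$estimates$var_LS)
  expect_equal(f2$standard_errors[["beta"]], f1$standard_errors[["beta"]])
})

test_that("divide-by-n variance estimators carry the finite-sample bias", {
  des <- simulation_design(n = 8, n_reps = 1500, seed = 2718)
  pop <- des$population
  vI <- vLS <- numeric(des$n_reps)
  for (r in seq_len(des$n_reps)) {
    fit <- fit_ml(generate_dataset(des, r))
    vI[r] <- fit$estimates$var_I
    vLS[r] <- fit$estimates$var_LS
  }
  # E[var_I_hat] = (n-1)/n * var, E[var_LS_hat] = (n-2)/n * var at n = 8
  expect_equal(mean(vI) / pop$var_I, 7 / 8, tolerance = 0.04)
  expect_equal(mean(vLS) / pop$var_LS, 6 / 8, tolerance = 0.04)
})

test_that("estimation requires both groups and enough subjects", {
  y <- matrix(rnorm(9), 3, 3)
  expect_error(fit_ml(longitudinal_data(y, c(0, 0, 0))),
               class = "bayesrma_estimation_error")
  expect_error(fit_ml(longitudinal_data(y[1:2, ], c(0, 1))),
               class = "bayesrma_input_error")
})
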