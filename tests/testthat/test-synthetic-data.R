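test_that("default population carries the simulation-design values", {
  pop <- default_population()
  expect_equal(pop$mu_I, 54.0900)
  expect_equal(pop$mu_LS, -12.4810)
  expect_equal(pop$mu_QS, 1.7590)
  expect_equal(pop$beta, 10.0080)
  expect_equal(pop$var_I, 593.6330)
  expect_equal(pop$var_LS, 199.3820)
  expect_equal(pop$var_QS, 134.6140)
})

test_that("group allocation is deterministic and both groups non-empty", {
  for (n in c(8, 14, 22)) {
    d <- generate_dataset(simulation_design(n = n, seed = 1), 1)
    expect_equal(sum(d$group), round(n * 0.5))
  }
  d <- generate_dataset(simulation_design(n = 78, group_allocation = 15 / 78,
                                          seed = 1), 1)
  expect_equal(sum(d$group), 15)
  expect_error(simulation_design(n = 8, group_allocation = 0.01),
               class = "bayesrma_input_error")
})

test_that("zero-variance population yields identical profiles within group", {
  pop <- parameter_set(54.09, -12.481, 1.759, 10.008, 0, 0, 0)
  d <- generate_dataset(simulation_design(pop, n = 4, seed = 9), 1)
  b <- build_contrast_basis()
  expected0 <- unname(drop(b$loading_matrix %*% c(pop$mu_I, pop$mu_LS, pop$mu_QS)))
  expected1 <- unname(drop(b$loading_matrix %*% c(pop$mu_I, pop$mu_LS + pop$beta, pop$mu_QS)))
  for (i in which(d$group == 0)) expect_equal(unname(d$outcomes[i, ]), expected0)
  for (i in which(d$group == 1)) expect_equal(unname(d$outcomes[i, ]), expected1)
})

test_that("generation is deterministic per (seed, replicate) and streams differ", {
  des <- simulation_design(n = 8, seed = 123)
  expect_identical(generate_dataset(des, 7), generate_dataset(des, 7))
  expect_false(identical(generate_dataset(des, 7)$outcomes,
                         generate_dataset(des, 8)$outcomes))
  des2 <- simulation_design(n = 8, seed = 124)
  expect_false(identical(generate_dataset(des, 7)$outcomes,
                         generate_dataset(des2, 7)$outcomes))
})

test_that("large-sample moments of generated scores match the population", {
  pop <- default_population()
  d <- generate_dataset(simulation_design(pop, n = 100000, seed = 31), 1)
  eta <- transform_to_growth_scores(d)
  mc_se <- sqrt(pop$var_I / 1e5)
  expect_lt(abs(mean(eta[, "I"]) - pop$mu_I), 3 * mc_se)
  # covariance of scores converges to the diagonal factor covariance
  S <- cov(cbind(eta[, "I"],
                 eta[, "LS"] - pop$beta * d$group,  # remove the group shift
                 eta[, "QS"]))
  expect_equal(diag(S), c(pop$var_I, pop$var_LS, pop$var_QS), tolerance = 0.03)
  offdiag <- S[upper.tri(S)]
  expect_lt(max(abs(offdiag)) / sqrt(pop$var_I * pop$var_LS), 0.02)
  # group difference in LS-score means converges to beta
  diff <- mean(eta[d$group == 1, "LS"]) - mean(eta[d$group == 0, "LS"])
  expect_lt(abs(diff - pop$beta), 3 * sqrt(pop$var_LS * (2 / 5e4)))
})

test_that("demo dataset is calibrated to the published ML estimates", {
  d <- demo_dataset()
  expect_equal(nrow(d$outcomes), 78)
  expect_equal(sum(d$group), 15)
  fit <- fit_ml(d)
  expect_equal(fit$estimates$mu_I, 54.0900, tolerance = 1e-10)
  expect_equal(fit$estimates$mu_LS, -12.4810, tolerance = 1e-10)
  expect_equal(fit$estimates$beta, 10.0080, tolerance = 1e-10)
  expect_equal(fit$estimates$var_LS, 199.3820, tolerance = 1e-8)
})
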