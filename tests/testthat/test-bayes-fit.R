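test_that("default priors are the diffuse software defaults", {
  pr <- default_priors()
  for (nm in c("mu_I", "mu_LS", "beta", "mu_QS")) {
    expect_equal(pr$structural[[nm]]$mean, 0)
    expect_equal(pr$structural[[nm]]$variance, 1e10)
    expect_true(is_proper(pr$structural[[nm]]))
  }
  for (nm in c("var_I", "var_LS", "var_QS")) {
    expect_equal(pr$variances[[nm]]$shape, -1)
    expect_equal(pr$variances[[nm]]$scale, 0)
    expect_false(is_proper(pr$variances[[nm]]))
  }
  expect_true(is_proper(inv_gamma_prior(0.5, 0.5)))
  expect_false(is_proper(inv_gamma_prior(0, 0)))
  expect_error(normal_prior(0, 0), class = "bayesrma_input_error")
  expect_error(inv_gamma_prior(0.5, -1), class = "bayesrma_input_error")
})

test_that("sampler is bit-reproducible from its seed", {
  d <- generate_dataset(simulation_design(n = 8, seed = 4), 1)
  cfg <- sampler_config(n_iterations = 500, seed = 99)
  ch1 <- gibbs_sample(d, config = cfg)
  ch2 <- gibbs_sample(d, config = cfg)
  expect_identical(ch1$draws, ch2$draws)
  ch3 <- gibbs_sample(d, config = sampler_config(n_iterations = 500, seed = 100))
  expect_false(identical(ch1$draws, ch3$draws))
})

test_that("flat-prior posterior centres on the data at large n", {
  d <- generate_dataset(simulation_design(n = 2000, seed = 21), 1)
  eta <- transform_to_growth_scores(d)
  ch <- gibbs_sample(d, priors = ig_priors(0.5, 0.5),
                     config = sampler_config(n_iterations = 4000, seed = 1))
  s <- summarize_posterior(ch)
  expect_equal(s$point[s$parameter == "mu_I"], mean(eta[, "I"]),
               tolerance = 0.01)
})

test_that("beta posterior matches a dense-grid integration oracle", {
  d <- generate_dataset(simulation_design(n = 8, seed = 8), 1)
  ch <- gibbs_sample(d, priors = ig_priors(0.5, 0.5),
                     config = sampler_config(n_iterations = 40000, seed = 17))
  draws <- ch$draws[, "beta"]
  oracle <- grid_beta_oracle(d, ig_shape = 0.5, ig_scale = 0.5)
  expect_lt(abs(mean(draws) - oracle$mean) / abs(oracle$mean), 0.02)
  expect_lt(abs(sd(draws) - oracle$sd) / oracle$sd, 0.02)
})

test_that("variance full conditional is the analytic inverse gamma (KS)", {
  d <- generate_dataset(simulation_design(n = 8, seed = 12), 1)
  eta <- transform_to_growth_scores(d)
  # Pin all structural parameters at 0 with a near-degenerate prior so the
  # variance draws are iid from their conditional.
  a <- 0.5; b <- 0.5
  pr <- ig_priors(a, b)
  for (nm in c("mu_I", "mu_LS", "beta", "mu_QS")) {
    pr$structural[[nm]] <- normal_prior(0, 1e-12)
  }
  ch <- gibbs_sample(d, priors = pr,
                     config = sampler_config(n_iterations = 200000, seed = 3))
  n <- 8
  ss_I <- sum(eta[, "I"]^2)  # SS around the pinned mean of zero
  ks <- suppressWarnings(
    ks.test(ch$draws[, "var_I"], pinvgamma, shape = a + n / 2,
            scale = b + ss_I / 2))
  expect_gt(ks$p.value, 0.01)
  ss_LS <- sum(eta[, "LS"]^2)
  ks2 <- suppressWarnings(
    ks.test(ch$draws[, "var_LS"], pinvgamma, shape = a + n / 2,
            scale = b + ss_LS / 2))
  expect_gt(ks2$p.value, 0.01)
})

test_that("prior- and data-dominance limits of the beta posterior", {
  d <- generate_dataset(simulation_design(n = 8, seed = 23), 1)
  # prior dominance: sigma0^2 -> 0 pulls the point estimate onto mu0
  pr <- set_prior(ig_priors(0.5, 0.5), beta = normal_prior(-5, 1e-6))
  s <- summarize_posterior(gibbs_sample(d, priors = pr,
                                        config = sampler_config(2000, seed = 2)))
  expect_equal(s$point[s$parameter == "beta"], -5, tolerance = 0.01)
  # data dominance: flat priors reproduce the ML point estimates
  big <- generate_dataset(simulation_design(n = 400, seed = 24), 1)
  ml <- fit_ml(big)
  s2 <- summarize_posterior(gibbs_sample(
    big, priors = default_priors(),
    config = sampler_config(10000, seed = 5, point_estimate_rule = "mean")))
  for (p in c("mu_I", "mu_LS", "beta", "mu_QS")) {
    expect_equal(s2$point[s2$parameter == p], ml$estimates[[p]],
                 tolerance = 0.1, ignore_attr = TRUE)
  }
})

test_that("posterior summaries behave on constructed chains", {
  cfg <- sampler_config(1000, seed = 1)
  fake <- function(draws) {
    structure(list(draws = draws, config = cfg, n = 8),
              class = "posterior_chains")
  }
  m <- matrix(7, 100, 1, dimnames = list(NULL, "beta"))
  s <- summarize_posterior(fake(m))
  expect_equal(s$point, 7)
  expect_equal(s$posterior_sd, 0)
  expect_equal(c(s$lower, s$upper), c(7, 7))
  set.seed(1)
  z <- matrix(rnorm(1e6), ncol = 1, dimnames = list(NULL, "beta"))
  s2 <- summarize_posterior(fake(z))
  expect_equal(s2$lower, -1.96, tolerance = 0.01)
  expect_equal(s2$upper, 1.96, tolerance = 0.01)
  expect_false(s2$significant)
  expect_equal(s2$one_tailed_p, 0.5, tolerance = 0.01)
  expect_error(summarize_posterior(fake(m[0, , drop = FALSE])),
               class = "bayesrma_input_error")
})

test_that("improper conditionals and single-group data are refused", {
  d <- generate_dataset(simulation_design(n = 8, seed = 2), 1)
  pr <- set_prior(default_priors(), var_I = inv_gamma_prior(-10, 0))
  expect_error(gibbs_sample(d, priors = pr, config = sampler_config(500)),
               regexp = "var_I", class = "bayesrma_estimation_error")
  single <- longitudinal_data(d$outcomes, rep(0, 8))
  expect_error(gibbs_sample(single, config = sampler_config(500)),
               class = "bayesrma_estimation_error")
})
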