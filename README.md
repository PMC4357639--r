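# bayesrma

Maximum-likelihood and Bayesian estimation of a three-occasion
repeated-measures growth model at very small sample sizes, with the
machinery to study *how small is too small*: configurable normal /
inverse-gamma priors, a prior-sensitivity grid, chain diagnostics for
variance-prior pathologies, and a Monte-Carlo harness for bias, coverage,
power and MSE.

It is written for applied longitudinal researchers working with rare
populations (the motivating case: posttraumatic-stress symptom courses in
burn survivors with vs. without mechanical ventilation, where a frequentist
power analysis demands more patients than exist in years of recruitment)
and for methodologists who want those small-sample claims reproducible
from synthetic data alone.

## The model

One outcome at three equally spaced occasions, re-expressed as a
constrained latent growth model: per subject, `y = Λη` with
`η = (I, LS, QS)'` the intercept, linear-slope and quadratic-slope scores,
`Λ` the transpose of the orthonormal polynomial contrast matrix
(rows `(1,1,1)/√3`, `(-1,0,1)/√2`, `(1,-2,1)/√6`), and

    I  ~ N(μ_I, σ²_I)
    LS ~ N(μ_LS + β·group, σ²_LS)
    QS ~ N(μ_QS, σ²_QS)

Factor covariances and occasion residuals are fixed at zero — seven
parameters in all, with the group coefficient `β` the target of inference.
Because the loadings are orthonormal, ML is closed-form and the Gibbs
sampler is exactly conjugate (normal updates for the means, a joint
bivariate-normal block for `(μ_LS, β)`, inverse-gamma
`IG(α₀ + n/2, υ₀ + SS/2)` updates for the variances).  Improper variance
priors such as the software-default `IG(-1, 0)` are accepted only when
every conditional is proper (`α₀ + n/2 > 0`).

See `vignettes/small-sample-growth-priors.Rmd` for the full methods
account.

## Worked example

Simulate one `n = 8` dataset from the default population (the
small-sample regime the package is about), then fit it both ways:

```r
library(bayesrma)

d <- generate_dataset(simulation_design(n = 8, seed = 3), 1)
fit_ml(d)
#> Closed-form ML fit (n=8)
#>        estimate       se    lower     upper
#> mu_I    60.4197   7.9760  44.7870   76.0523
#> mu_LS  -13.7751   4.7349 -23.0554   -4.4949
#> mu_QS   -1.9296   4.0825  -9.9311    6.0719
#> beta    15.9014   6.6962   2.7771   29.0257
#> var_I  508.9323 254.4662  10.1878 1007.6769
#> var_LS  89.6781  44.8391   1.7952  177.5610
#> var_QS 133.3323  66.6661   2.6690  263.9955
#> beta significant at 0.05: TRUE

priors <- set_prior(default_priors(),
                    var_I  = inv_gamma_prior(0.5, 0.5),
                    var_LS = inv_gamma_prior(0.5, 0.5),
                    var_QS = inv_gamma_prior(0.5, 0.5))
summarize_posterior(gibbs_sample(d, priors = priors,
                                 config = sampler_config(10000, seed = 1)))
#> Posterior summary (point = configured rule, 95% PPI):
#>  parameter    point posterior_sd    lower     upper significant one_tailed_p
#>       mu_I  60.3380       9.1304  42.3740   78.3878        TRUE       0.0000
#>      mu_LS -13.8290       5.8399 -25.3503   -1.8599        TRUE       0.0138
#>      mu_QS  -2.0048       4.5800 -11.1711    7.1620       FALSE       0.3140
#>       beta  15.9471       8.3541  -0.3844   32.8182       FALSE       0.0270
#>      var_I 549.5542     483.1691 233.3373 1858.8755        TRUE       0.0000
#>     var_LS 112.4006     101.5441  44.8813  408.2856        TRUE       0.0000
#>    var_QS 143.1173     123.2243  60.8003  476.4174        TRUE       0.0000
```

The ML Wald interval for `beta` excludes zero while the 95% posterior
probability interval under proper-but-diffuse-on-`beta` priors does not:
at `n = 8` the Bayesian interval is wider and better calibrated (its
coverage sits near 0.94 where the Wald interval's sits near 0.86 — the
Monte-Carlo module computes exactly this), so single small-sample
"significant" ML results deserve suspicion.  Informative priors recover
power; `run_prior_grid()` and `run_power_grid()` quantify how much, and at
what sensitivity-to-misspecification cost:

```r
grid <- run_prior_grid(demo_dataset(), mu0_grid = c(5, 0, -5, -10),
                       var0_grid = c(1000, 100, 20, 5, 1),
                       config = sampler_config(4000, seed = 11))
```

A thin command-line wrapper over the same functions is installed as
`exec/bayesrma` (subcommands `simulate`, `fit-ml`, `fit-bayes`,
`mc-study`, `sensitivity`, `diagnose`; every run writes a
`*.manifest.json` with the fully resolved configuration and seed).

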