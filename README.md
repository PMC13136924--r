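# dicph

Semiparametric proportional-hazards regression when **both the outcome and a
covariate are interval-censored** event times, as in HIV
suppression–rebound studies: the time to viral rebound after a treatment
interruption (outcome `T2`) is regressed on the time to viral suppression
after starting therapy (covariate `T1`), and both times are only known to
lie between two clinic visits, `(L, R]`, with `R = Inf` when the event had
not occurred by the last visit.

The model is

```
lambda_2(t | T1, z2) = lambda_20(t) * exp(beta1 * T1 + beta2' z2)   # outcome
lambda_1(t | z1)     = lambda_10(t) * exp(gamma' z1)                # covariate event
```

with both baseline cumulative hazards left as unspecified step functions
jumping at the pooled bracket endpoints. Because `T1` is interval-censored,
the Cox partial likelihood is unavailable; the package computes the
nonparametric maximum likelihood estimator by an EM algorithm that
represents the interval-censoring events through latent Poisson counts,
giving closed-form M-step updates for the `T2` baseline increments and
small concave Newton problems for the coefficients (compiled core).
Inference uses the inverse observed information; participants contributing
several suppression–rebound episodes are handled by an independence
composite likelihood with sandwich or cluster-bootstrap variances.
Simulators for monitoring schedules, Weibull and piecewise-hazard event
times and Gaussian-copula clustered episodes, plus midpoint-imputation
comparator fits and a replicated-study driver, round out the package.

## Worked example

```r
library(dicph)

cfg <- dic_scenario("study1", scenario = "1.1", n = 200)  # Weibull baselines (t/3)^2, (t/10)^5
d   <- simulate_dic(cfg, seed = 1)
d
#> <dic_data> 200 episodes, 200 cluster(s)
#>   T1: 200 interval-censored, 0 right-censored
#>   T2: 200 interval-censored, 0 right-censored, 0 unobserved (o2 = 0)
#>   covariates: p1 = 1, p2 = 1

fit <- dic_fit(d)
summary(fit)
#> <dic_fit>
#>   log-likelihood: -822.14803  EM iterations: 5000  [NOT converged]
#>      beta1    beta2_1    gamma_1
#>  0.3312069  0.9644041 -0.4595249
#>
#> Variance method: model
#>          Estimate Std. Error   CI 2.5% CI 97.5%   p-value
#> beta1    0.331207   0.058118  0.217297   0.4451 1.206e-08 ***
#> beta2_1  0.964404   0.162745  0.645424   1.2834 3.107e-09 ***
#> gamma_1 -0.459525   0.151535 -0.756533  -0.1625  0.002426 **
```

`beta1 = 0.33` is the estimated log hazard ratio of rebound per unit (month)
of suppression time — `exp(0.33) ≈ 1.39`, a 39% higher rebound hazard per
additional month to suppression (true value 0.3 in this design, well inside
the 95% CI); `beta2` and `gamma` are the covariate effects in the two
models, and each fit also carries the estimated baseline cumulative hazards
(`baseline_hazard(fit, 1)`, `baseline_hazard(fit, 2)`). The `[NOT
converged]` flag refers to the strict joint criterion on the
log-likelihood *and* every baseline increment: the regression coefficients
stabilize within a few hundred EM iterations, while mass keeps
consolidating between neighbouring baseline jump points far longer — see
the vignette's numerical-choices section.

Clustered data use the same fitter with robust variances:

```r
dcl <- simulate_dic(dic_scenario("clustered", n = 150, rho = 0.5), seed = 2)
fcl <- dic_fit(dcl)
summary(fcl, variance = "sandwich")
```

Midpoint-imputation baselines (`midpoint_a_fit()`, `midpoint_b_fit()`) and
the replicated-study driver (`run_study()`) reproduce the comparison and
robustness experiments; see the vignette in `vignettes/` for the model,
algorithm, and every numerical convention.

A thin command-line wrapper is installed with the package
(`system.file("exec", "dicph", package = "dicph")`) with subcommands
`simulate`, `fit`, `compare`, and `experiment` over CSV files.

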