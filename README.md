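# lmmborrow

Dynamic borrowing of a historical control arm in Bayesian analyses of
longitudinal two-arm clinical trials.

## The problem

Trials with repeated continuous outcomes are commonly analysed with the
constrained longitudinal data analysis (cLDA) linear mixed model

$$y_{it} = \beta_0 + \beta_1\,t + \beta_2\,\mathrm{trt}_i\,t + b_{0i} + b_{1i}\,t + \varepsilon_{it},
\qquad b_i \sim N(0, G),\ \varepsilon_{it} \sim N(0,\sigma^2),$$

where randomisation constrains the baseline mean to be equal across arms,
so the treatment effect is the treatment-by-time interaction $\beta_2$.
When a comparable historical control arm exists, borrowing it can raise
power without enlarging the trial — but naive pooling inflates the type I
error whenever the studies differ. `lmmborrow` implements the *dynamic*
borrowing methods that let the data set the weight of the historical arm:

* **marginal modified power prior (MPP)** — the historical *marginal*
  likelihood (random effects integrated out) is raised to a power
  $\alpha \in [0,1]$ that is itself given a Beta prior and estimated;
  the power prior is normalised by the scaling constant
  $c(\alpha) = \int L_0(\theta)^\alpha p_0(\theta)\,d\theta$, estimated by
  path sampling (thermodynamic integration) on a grid of powers with
  linear interpolation in between;
* **conditional MPP** — the historical likelihood *given* the random
  effects is tempered; the historical random effects are then integrated
  out analytically (tempering a Gaussian rescales its residual variance to
  $\sigma^2/\alpha$), which avoids sampling hundreds of latent effects;
* **commensurate prior** — the historical arm keeps its own parameters and
  the current study's shared coefficients get a normal prior centred on
  the historical ones, with an estimated commensurability covariance;
* **pooling** and **no borrowing** as reference analyses.

A trial simulator with study-level random intercepts and slopes (the
between-study heterogeneity model), a replication harness, and
operating-characteristics metrics (type I error, power, calibrated power,
bias, posterior SD, MSE, Monte Carlo SEs, paired McNemar tests) round out
the package. Posterior computation is a purpose-built compiled sampler:
exact conjugate Gibbs updates for all fixed effects combined with blocked
adaptive random-walk Metropolis for variance components and the power
parameter. See the methods vignette
(`vignettes/historical-borrowing-methods.Rmd`) for the models, priors and
numerical choices.

## Worked example

Simulate a homogeneous trial with a true treatment effect of 0.36 and
compare no borrowing with the marginal MPP:

```r
library(lmmborrow)

trial <- simulate_trial(scenario_spec("No", effect = 0.36), seed = 33)
cfg <- borrow_config(seed = 1)        # 4 chains x 2000 iterations

fit0 <- fit_no_borrowing(trial$current, cfg)
print(fit0)
```

```
Bayesian cLDA linear mixed model — no borrowing 
  current: 200 subjects / 1200 observations
            mean     sd   q2.5  q97.5  rhat  ess
intercept 2.0042 0.0646 1.8766 2.1339 0.999 4000
time      1.0646 0.1160 0.8326 1.2878 1.000 4000
trt_time  0.3364 0.1462 0.0466 0.6186 0.999 4000
sigma     1.0181 0.0245 0.9704 1.0694 1.000 1696
```

```r
fit1 <- fit_marginal_mpp(trial$current, trial$historical, cfg)
print(fit1)
print(test_treatment_effect(fit1))
```

```
Bayesian cLDA linear mixed model — marginal modified power prior 
  current: 200 subjects / 1200 observations; historical: 100 subjects
            mean     sd   q2.5  q97.5  rhat  ess
intercept 1.9939 0.0557 1.8827 2.1061 0.999 3854
time      1.0239 0.0921 0.8471 1.2057 1.001 3906
trt_time  0.3856 0.1245 0.1368 0.6304 1.000 3789
sigma     1.0071 0.0213 0.9686 1.0505 1.002 1252
alpha     0.5944 0.2314 0.1677 0.9755 1.001 1214
Treatment effect (treatment-by-time): 0.3856 (SD 0.125 )
  95% CrI: (0.1368, 0.6304) -> significant
```

Reading the output: the treatment-by-time coefficient (`trt_time`)
estimates how much faster the treated arm's mean outcome grows per unit
time; the simulation truth is 0.36. Borrowing the 100 historical controls
shrinks its posterior SD relative to no borrowing — the posterior SD is the
package's working measure of how much historical information was used. The
`alpha` row summarises the estimated power parameter: the weight (0 =
ignore, 1 = pool) given to the historical likelihood. `rhat`/`ess` are
split-chain convergence diagnostics; values below 1.05 and above 400
indicate a trustworthy fit.

Operating characteristics over replicated trials:

```r
fast <- borrow_config(chains = 2, iterations = 1000, burn_in = 500,
                      grid_step = 0.05, grid_iterations = 150)
oc <- run_scenario(c("none", "pool", "mmpp"),
                   scenario_spec("RI+Moderate", effect = 0),
                   R = 100, base_seed = 1, config = fast)
print(oc)   # type I error per method with Monte Carlo SEs
```

A command-line front-end (`inst/cli/lmmborrow`) exposes the same pipeline
as `simulate`, `fit`, `run-study` and `report` subcommands; every run
directory receives a `manifest.json` with the seed, configuration and
output hashes.

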