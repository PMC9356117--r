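---
title: "Dynamic borrowing of historical controls in longitudinal trials: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic borrowing of historical controls in longitudinal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A two-arm randomised trial measures a continuous outcome repeatedly over
time, and a historical control arm from a comparable earlier trial is
available. Simply pooling the historical controls with the current data
increases power but inflates the type I error rate whenever the two studies
differ systematically; ignoring them wastes information. *Dynamic borrowing*
methods let the data determine how much historical information to use.
`lmmborrow` implements two variants of the modified power prior (MPP) for
the linear mixed model, the commensurate prior, and the pooling and
no-borrowing baselines, together with a trial simulator and an
operating-characteristics harness.

## The outcome model

Both studies are analysed with the constrained longitudinal data analysis
(cLDA) linear mixed model. For subject $i$ at time $t$,

$$y_{it} = \beta_0 + \beta_1\,t + \beta_2\,\mathrm{trt}_i\,t
  + b_{0i} + b_{1i}\,t + \varepsilon_{it},$$

with $(b_{0i}, b_{1i})^\top \sim N(0, G)$,
$\varepsilon_{it} \sim N(0, \sigma^2)$. Because randomisation guarantees
equal baseline means, there is no treatment main effect: the treatment acts
only through the treatment-by-time interaction $\beta_2$, which is the
parameter of inferential interest. Baseline covariates may be added to the
shared fixed-effects block. Time is treated as continuous with a linear
trend; a categorical-time variant is not implemented. Missing visits are
simply absent rows and are handled by the likelihood; no imputation is
performed.

Writing $\beta_C$ for the shared coefficients (intercept, covariates, time)
and $\beta_T$ for the interaction, the historical control arm follows the
same model without any treatment term.

## Conditional versus marginal tempering

The likelihood of an LMM exists in two forms: *conditional* on the random
effects, $y_i \mid b_i \sim N(X_i\beta + Z_i b_i,\ \sigma^2 I)$, and
*marginal*, $y_i \sim N(X_i\beta,\ Z_i G Z_i^\top + \sigma^2 I)$. Raising
either historical likelihood to a power $\alpha \in [0, 1]$ yields two
distinct power priors:

* **marginal MPP** — the historical term is
  $\alpha\,\ell_0(\theta)$ with $\ell_0$ the marginal log-likelihood;
* **conditional MPP** — the likelihood given the historical random effects
  is tempered and the random effects are then integrated out. Tempering a
  Gaussian rescales its residual variance, so the integral is available in
  closed form:
  $$\log \int N(y_0; X_0\beta_C + Z_0 b,\ \sigma^2 I)^\alpha\,
      N(b; 0, G)\,db
    = \tfrac{(1-\alpha)m}{2}\log(2\pi\sigma^2) - \tfrac{m}{2}\log\alpha
      + \log N\!\big(y_0;\ X_0\beta_C,\ Z_0 G Z_0^\top +
        \tfrac{\sigma^2}{\alpha} I\big).$$
  The analytic integration replaces sampling of hundreds of historical
  random effects, which is both faster and easier to converge. As
  $\alpha \to 0^+$ the kernel tends to 0 (the tempered likelihood tends to
  one and the random-effect density integrates to one), which is the value
  used at $\alpha = 0$.

At equal fixed $\alpha$ the conditional variant contributes
$X_0^\top (Z_0 G Z_0^\top + \sigma^2 I/\alpha)^{-1} X_0$ of information
about $\beta_C$ versus $\alpha\,X_0^\top (Z_0 G Z_0^\top + \sigma^2
I)^{-1} X_0$ for the marginal variant; the former dominates in the Loewner
order, so the conditional MPP borrows more at the same power. The test
suite checks this as a posterior-SD ordering at known $(G, \sigma^2)$.

## The scaling constant and path sampling

Treating $\alpha$ as unknown requires normalising the power prior by
$c(\alpha) = \int L_0(\theta)^\alpha p_0(\theta)\,d\theta$, which has no
closed form for LMMs. The package estimates it by thermodynamic
integration: $d \log c / d\alpha$ equals the expectation, under the
$\alpha$-tempered historical posterior, of the $\alpha$-derivative of the
tempered log kernel. For the marginal MPP that derivative is $\ell_0$
itself; for the conditional MPP it is obtained analytically,

$$\frac{\partial}{\partial\alpha}
  = -\tfrac{m}{2}\log(2\pi\sigma^2) - \tfrac{m}{2\alpha}
    + \tfrac{\sigma^2}{2\alpha^2}\big(\operatorname{tr} V_\alpha^{-1}
    - \lVert V_\alpha^{-1} r\rVert^2\big),
  \qquad V_\alpha = Z_0 G Z_0^\top + \tfrac{\sigma^2}{\alpha} I,$$

with limit $-\tfrac{m}{2}\log(2\pi\sigma^2) - (\operatorname{tr} Z_0 G
Z_0^\top + \lVert r\rVert^2)/(2\sigma^2)$ at $\alpha = 0$ (the prior
expectation of the conditional log-likelihood). Both forms are verified in
the tests against finite differences and 1-D quadrature.

Estimation runs in two steps. **Step 1** walks a grid of powers (default
$0, 0.02, \dots, 1$, one short chain per node — 400 iterations with the
first 100 discarded, a length chosen so the random-walk sampler's per-node
Monte Carlo error matches what an efficient gradient-based sampler reaches
with a 100-iteration node) and integrates the node means by the trapezoidal rule,
anchored at $\log c(0) = 0$; each node warm-starts from the previous
node's final state, a standard thermodynamic-integration practice that
removes most transient bias; the $\alpha = 0$ node is drawn directly from
the (proper) prior. **Step 2** samples $(\theta, \alpha)$ jointly, with
$\log c(\alpha)$ between nodes obtained by linear interpolation. Interpolation
is linear on the $\log c$ scale by default — the quantity actually added to
the log posterior, and numerically stable since $\log c$ spans hundreds of
units — with interpolation on the $c$ scale (computed stably in logs)
available as an option.

Two properties of the grid are tested: $\log c$ is convex in $\alpha$ (its
second derivative is the variance of the integrand) and, on a conjugate toy
model with known error variance and no random effects, the whole grid
matches a closed-form expression to within 2%. Trapezoidal discretisation
error concentrates near $\alpha = 0$, where the integrand is steepest; it
is negligible at the default 0.02 step for the priors used here.

## Priors

Defaults follow the simulation settings used throughout the package:

| parameter | prior | default |
|---|---|---|
| fixed effects | g-prior $N(0,\ g\sigma^2 (X^\top X)^{-1})$ | $g$ = number of current-study observations |
| random-effect SDs $\tau$ | half-normal$(0, s)$ | $s = 1$ |
| random-effect correlation | LKJ$(\eta)$ | $\eta = 1$ |
| error SD | half-normal$(0, s)$ | $s = 4$ |
| power parameter $\alpha$ | Beta$(a, b)$ | $(1, 1)$; sensitivity $(1, 2)$ |
| commensurability SDs | half-normal$(0, s)$ | $s = 1$ |

Half-normal$(0, s)$ is read with $s$ as the scale (the SD of the underlying
normal), the convention of mainstream Bayesian software. $G$ is decomposed
as $\operatorname{diag}(\tau)\,\Omega\,\operatorname{diag}(\tau)$; no
inverse-Wishart option is provided.

Three points where the design was genuinely open:

* **Which design matrix the g-prior uses.** All models fitted to current
  data (no borrowing, pooling, both MPPs) use the current-study stacked
  design including the interaction column, with $g$ equal to the current
  observation count — each coefficient block receives a unit-information
  prior from the study it describes, and, importantly, the fixed-power
  reduction identities ($\alpha = 0$ reproduces no borrowing, $\alpha = 1$
  reproduces pooling) then hold exactly at the kernel level, which the test
  suite exploits. In the commensurate model $\beta_{0C}$ gets the
  historical-design g-prior with $g$ the historical observation count, and
  $\beta_T$ the marginal of the current-design g-prior; $\beta_C$ needs no
  extra prior because the commensurate link is its prior. In Step 1 of the
  path sampling, the prior for $\beta_C$ is the corresponding marginal of
  the current-design g-prior.
* **Credible intervals are equal-tailed** (2.5% and 97.5% quantiles of the
  pooled post-burn-in draws), not HPD; the treatment effect is declared
  significant when the 95% interval excludes zero.
* **The commensurate model** gives the historical arm its own
  $(\beta_{0C}, G_0, \sigma_0^2)$ and links the studies only through
  $\beta_C \sim N(\beta_{0C}, \Sigma_{\beta_C})$, with
  $\Sigma_{\beta_C}$ decomposed into half-normal SDs and an LKJ(1)
  correlation. Variance components are not borrowed.

## Posterior computation

The sampler family most often used for such models is gradient-based HMC.
This package instead ships a purpose-built blocked sampler in compiled
code, designed around a property of every model implemented here: *all
fixed effects are conditionally Gaussian*. The historical terms of both
MPP variants are Gaussian kernels in $\beta_C$ (with weight $\alpha$, or
with residual variance $\sigma^2/\alpha$), and the commensurate link is
Gaussian in $(\beta_C, \beta_{0C})$. Every iteration therefore draws the
full coefficient block exactly from its multivariate normal full
conditional (conjugate Gibbs), and only the low-dimensional remainder —
$\tau$, $\Omega$, $\sigma$, $\alpha$ and, for the commensurate model, the
historical variance components and the link covariance — is updated by
adaptive random-walk Metropolis on unconstrained scales (log SDs, atanh
correlations, logit power) with Haario covariance adaptation,
Robbins–Monro step-size tuning, and several Metropolis sweeps plus one
random-coordinate refreshment per Gibbs iteration. Adaptation is frozen at
the end of burn-in so the post-burn-in kernel is a fixed Markov kernel.

The `target_accept` configuration value (default 0.95, the natural setting
for gradient-based samplers and the value used for the conditional MPP's
difficult posteriors) is interpreted by the random-walk sampler as a
request for careful adaptation and mapped to the random-walk optimum of
0.35; values at or below 0.45 are used literally.

MPP chains start from dispersed random powers (logit-uniform), so a
genuinely bimodal power-parameter posterior — an intrinsic possibility for
the conditional MPP under moderate heterogeneity — shows up either as
disagreeing chains (flagged by split-$\hat R$) or as two separated modes in
the pooled draw histogram, which the package detects and reports in the
fit's power-parameter summary rather than treating as an error.

Convergence is summarised per parameter by split-$\hat R$ and a bulk
effective sample size (chain-averaged autocorrelations with Geyer's initial
monotone sequence); the replication harness excludes (and counts) fits with
any monitored $\hat R \ge 1.05$ and flags a run when exclusions reach 2%.
All randomness flows from one base seed, from which per-chain and
per-grid-node streams are derived; a fit is bit-reproducible given its
configuration.

Numerical safeguards: per-subject marginal covariances are handled by dense
Cholesky factorisation (subjects are grouped by identical random-effects
design so each distinct covariance is factorised once per evaluation);
non-positive-definite proposals are rejected rather than repaired; states
with an SD below $10^{-6}$ are rejected to keep factorisations away from
singularity (truncating negligible prior mass); and the degenerate
$\alpha = 0$ endpoints use the analytic limits described above.

## The trial simulator

`simulate_trial()` generates the study conditions used throughout the
package's tests: a current trial with 100 treated and 100 control subjects
plus a historical arm of 100 controls, each subject observed at times
$0, 0.2, \dots, 1$ (six visits), from

$$y_{itj} = \beta_0 + \beta_1 t + \beta_2\,\mathrm{trt}\,t
  + b_{0ij} + b_{1ij} t + d_{0j} + d_{1j} t + \varepsilon_{itj},$$

with $\beta_0 = 2$, $\beta_1 = 1$, subject random effects with variances
$0.25$ and zero covariance, unit error variance, and $\beta_2 = 0$ (null)
or $0.36$ (alternative). Between-study heterogeneity enters through
study-level random intercepts and slopes $d_j \sim N(0,
\operatorname{diag}(\sigma_{d0}^2, \sigma_{d1}^2))$, drawn independently
for each study (an exchangeable-parameters design: operating
characteristics average over historical trials rather than conditioning on
one). Seven named scenarios map heterogeneity levels to variances: none
$(0,0)$; random intercept only at $0.01 / 0.09 / 0.16$; random intercept
and slope at $(0.01, 0.01) / (0.09, 0.09) / (0.16, 0.16)$.

What the generator deliberately does *not* emulate: fixed systematic bias
between studies (only exchangeable drift), missing visits or dropout,
unequal sample sizes or visit schedules between studies, baseline
covariates, and non-Gaussian outcomes. Passing tests therefore certify the
estimators under exchangeable heterogeneity with complete balanced data —
not robustness to informative missingness or structurally biased controls.

## Operating characteristics

`run_scenario()` fits every requested method to the *same* simulated trial
pair per replicate (replicate $r$ uses seed `base_seed` $+ r$), so methods
can be compared by McNemar's paired test on rejection indicators (exact
doubled-binomial below 25 discordant pairs, continuity-corrected chi-square
otherwise). Reported metrics are the rejection rate (type I error under the
null, power under the alternative) with binomial Monte Carlo SE
$\sqrt{p(1-p)/R}$, bias, mean posterior SD (the package's proxy for the
amount of borrowing), and MSE, each with Monte Carlo SEs. *Calibrated
power* re-thresholds the two-sided posterior tail probability
$p_r = 2\min\{\Pr(\beta_T<0), \Pr(\beta_T>0)\}$ at the empirical 5%
quantile of its null distribution, forcing every method to the same type I
error before comparing power — an equivalent but cheaper decision rule than
re-tuning interval levels.

### Summarising the power parameter

Fits with a free power report its posterior mean, median, IQR and a
histogram mode (bins of width 0.02 on $[0, 1]$, reported as exactly 1 or 0
when the maximal bin abuts a boundary), plus the bimodality flag. The mode
deserves a caveat: when the two studies agree, the posterior of $\alpha$
typically rises and then plateaus towards 1, and a maximal-bin estimator
over a near-flat plateau is decided by Monte Carlo noise among many
near-equal bins. A sketch of why the plateau arises: integrating the shared
parameters out, the marginal posterior of $\alpha$ behaves like
$e^{-\Delta\alpha}\,\alpha^{d/2}$, where $d$ is the dimension of the
parameters entering the scaling constant and $\Delta \ge 0$ measures how
much better the historical data fit their own optimum than the shared one;
under exact homogeneity the sampling distribution of $\Delta$ straddles
$d/2$, so the mode sits at the boundary for some datasets and just inside
it for others. The mean and median are the stable summaries; the mode is
reported because boundary concentration is the classical signature of full
borrowing.

## Problem sizes used by the test suite

The full factorial study (7 heterogeneity levels × 2 effects × 5 methods ×
500 replicates at 4 chains × 2000 iterations) is a cluster-scale
computation. The package's own test suite runs the same machinery at
reduced scale, chosen once as the smallest sizes at which the checked
contrasts exceed their Monte Carlo noise: 100–200 replicates with 2 chains
× 1000 iterations and a 0.05 grid step for replications of the headline
operating characteristics, full 100-per-arm trials for those, and smaller
trials (15–60 per arm) for identities and oracle checks. Full-scale
settings remain the package defaults.

## Known limitations

* One historical control arm; multiple historical studies and
  meta-analytic-predictive priors are out of scope.
* Gaussian outcomes only; the conditional-integration trick that powers
  both the conditional MPP and the path-sampling integrand has no
  closed form in GLMMs.
* Residual covariance is $\sigma^2 I$; no serial correlation structures.
* The commensurate model borrows location parameters only, not
  (co)variances.
* The random-walk sampler, while adequate for these posteriors (and
  validated against a frequentist REML oracle and conjugate closed forms),
  mixes more slowly per iteration than gradient-based samplers; the
  conjugate Gibbs step for all fixed effects is what keeps the parameter
  of interest efficient.
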