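---
title: "Methods: models, estimation, and design choices in uoa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimation, and design choices in uoa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uoa)
```

## The problem

In a nested laboratory design a treatment is applied to subjects (the
experimental units), but each subject contributes several samples and each
sample several replicate measurements. Measurements from the same subject
are correlated; any analysis that pools them as independent observations
tests a subject-level treatment against within-subject variability and
therefore rejects far too often. This vignette records the models `uoa`
fits, the numerical methods behind them, and the choices made where more
than one defensible option existed.

## The nested Gaussian model

`fit_nested_lmm()` fits

$$y_{ijk} = \mathbf{x}_i^\top\beta + b_i + s_{ij} + \varepsilon_{ijk},
\qquad b_i \sim N(0, \sigma_P^2),\;
s_{ij} \sim N(0, \sigma_S^2),\;
\varepsilon_{ijk} \sim N(0, \sigma_\varepsilon^2),$$

for subject $i$, sample $j$ and replicate $k$, all components independent,
with the treatment group as the only fixed effect. All three standard
deviations are in the units of the outcome. The subject-level intraclass
correlation $\mathrm{ICC}_P = \sigma_P^2 / (\sigma_P^2 + \sigma_S^2 +
\sigma_\varepsilon^2)$ is the correlation between two randomly chosen
observations on the same subject; independence of all observations is the
special case $\mathrm{ICC} = 0$.

### REML estimation

The default criterion is restricted maximum likelihood, which estimates the
variance components after removing the degrees of freedom used by the fixed
effects and is the standard choice when variance components are themselves
of interest. Writing the marginal covariance as $\sigma_\varepsilon^2
W(\gamma)$ with variance ratios $\gamma_P = \sigma_P^2 /
\sigma_\varepsilon^2$ and $\gamma_S = \sigma_S^2 / \sigma_\varepsilon^2$,
both $\beta$ (by generalised least squares) and $\sigma_\varepsilon^2$ (as
$\mathrm{RSS}/(n-p)$ under REML, $\mathrm{RSS}/n$ under ML) have closed
forms at fixed $\gamma$, leaving a two-parameter (or one-parameter, for a
subject-only structure) optimisation over $\log\gamma$.

Numerical choices:

* **Parameterisation and optimiser.** L-BFGS-B on $\log\gamma$ with box
  $[-30, 30]$; the log scale keeps the parameter space unconstrained and
  the box gives a well-defined boundary state. Convergence uses the
  optimiser's default relative-improvement criterion tightened to
  `factr = 1e4`.
* **Starting values.** ANOVA method-of-moments estimates computed from the
  pooled within-sample, between-sample and between-subject mean squares,
  floored at $10^{-3}\,\mathrm{var}(y)$ so the start is always interior. On
  balanced designs with interior optima REML coincides with these
  moment estimators, which the test suite exploits as an independent
  oracle.
* **Exact block linear algebra.** The marginal covariance is block diagonal
  by subject, so the likelihood is accumulated from per-subject Cholesky
  factorisations ($[X\;y]^\top W^{-1} [X\;y]$ and $\log|W|$), with factors
  cached per within-subject design pattern. This is exact — identical to
  the dense computation — and makes balanced simulation loops cheap,
  because every subject shares one pattern.
* **Boundary behaviour.** A ratio driven to the lower box edge
  ($\log\gamma < -15$, i.e. an SD about $5\times10^{-4}$ of the residual
  SD) is reported as essentially zero with a `boundary` flag and a
  warning, not as an error; its Wald interval is `NA` and inference
  effectively degrades to the model without that level.

### Inference

* **Fixed effects.** Treatment is applied at the subject level, so its
  estimate is tested against the between-subject stratum with containment
  degrees of freedom $n_\mathrm{subjects} - n_\mathrm{groups}$ (t
  distribution). On any balanced design this makes the mixed-model
  estimate, standard error, t statistic, df and CI *identical* to the
  t-test on subject means — a property the acceptance suite checks to
  $10^{-6}$ across simulated datasets. Satterthwaite or Kenward–Roger
  approximations are deliberately out of scope: for subject-level
  treatments the containment df is exact in the balanced case and
  conservative otherwise.
* **Variance components.** Wald intervals on the $\log\sigma$ scale,
  back-transformed, using a central-difference Hessian
  (`pracma::hessian`) of the restricted log-likelihood in
  $\log\sigma$. Profile-likelihood intervals would also have been
  defensible; the Wald-on-log construction matches common mixed-model
  practice, is cheap, and agrees with an independent implementation
  (`nlme::lme`'s `intervals()`) on the packaged data.
* **Random-structure comparison.** `lrt_random_structure()` computes
  $\mathrm{LRT} = 2(\ell_\mathrm{full} - \ell_\mathrm{reduced})$ between
  REML fits with identical fixed effects (refused otherwise), floored at
  zero. Because the null hypothesis $\sigma_S = 0$ lies on the parameter
  boundary, the $\chi^2_1$ reference is conservative; both the naive
  $\chi^2_1$ p-value and the 50:50 $\chi^2_0{:}\chi^2_1$ mixture p-value
  are reported. A simulation test confirms the naive reference rejects at
  or below the nominal rate under the null.

## The binomial mixed model

`fit_logistic_glmm()` maximises the marginal likelihood

$$\prod_i \int \prod_j \binom{n_{ij}}{k_{ij}}
p_{ij}(b)^{k_{ij}} (1-p_{ij}(b))^{n_{ij}-k_{ij}}\,
\phi(b; 0, \sigma^2)\, db,
\qquad \mathrm{logit}\, p_{ij}(b) = \mathbf{x}_i^\top\beta + b,$$

over $(\beta, \log\sigma)$. The aggregated events-out-of-trials likelihood
is used directly (identical to the Bernoulli expansion up to a constant).
Each subject's integral is approximated adaptively: the conditional mode
$\hat b_i$ is found by Newton iteration (step tolerance $10^{-10}$, at most
50 steps), the integrand is centred and scaled there, and evaluated with
`n_quad` Gauss–Hermite nodes. One node gives the Laplace approximation,
which is the default because it is the common default of mixed-model
software for binomial responses, and because the packaged count data were
analysed that way: increasing `n_quad` to 25 moves the log-likelihood
monotonically by less than 0.1 and the log-odds coefficients by less than
0.02, so the Laplace fit is reported with that documented accuracy. Wald
standard errors come from the numerically differentiated observed
information; at a boundary fit ($\sigma \approx 0$, flagged) the
$\beta$ block alone is inverted and the fit coincides with the IRLS GLM.

Predicted probabilities from `predict_probability()` are *conditional* on
the random effect (default $b = 0$, a typical subject), not
population-averaged: the conditional reading keeps
$\mathrm{logit}(p_1) - \mathrm{logit}(p_0)$ exactly equal to the fitted
log odds ratio, which is how the accompanying odds-ratio output should be
interpreted.

## Classical analyses

The pooled and subject-based t-tests are implemented directly from the
textbook formulas (pooled variance, $sed = s\sqrt{1/n_1 + 1/n_2}$),
two-sided throughout, and verified against an independently coded oracle
on hundreds of random datasets. Only the mean is offered as a subject
summary; precision-weighted summaries are deliberately not implemented
(the interface admits future statistics, but an unweighted mean on
unbalanced data triggers an explicit warning instead of a silent choice of
weights). The naive logistic GLM uses IRLS with a relative log-likelihood
tolerance of $10^{-10}$ and at most 100 iterations, detects separation by
coefficient divergence, and on the group-saturated model agrees with the
2×2 odds-ratio formula to machine precision — another dual-route check in
the tests. Group differences and odds ratios are reported with the first
group in sort order as reference unless `reference` is set.

## Design calculators and the Monte-Carlo engine

`vif()`, `sample_size_two_group()` and `inflate_for_clustering()` are the
standard closed forms ($\mathrm{VIF} = 1 + (m-1)\,\mathrm{ICC}$;
$n = 2\sigma^2 (z_{\alpha/2}+z_\beta)^2/d^2$).
`resource_equation_check()` applies nested-ANOVA df bookkeeping with the
≥ 15 error-df rule of thumb per stratum.

`simulate_nested_dataset()` draws balanced Gaussian data
$y = \mu + \mathrm{effect}\cdot[\text{group 1}] + b_P + b_S +
\varepsilon$. It emulates exactly the features the models assume —
Gaussian components, constant variances, independence across levels,
balance — and none they do not (no outliers, heteroscedasticity, temporal
autocorrelation, or informative missingness). Passing simulation tests
therefore validates the estimators under their own assumptions; they say
nothing about robustness to violations, which is why the residual
diagnostics (`lmm_diagnostics()`: per-subject boxplot statistics and a
Q–Q series scaled by the fitted residual SD) exist.

`run_simulation_study()` applies the naive, subject-based, and mixed
analyses to each replicate and aggregates rejection rate (with Monte-Carlo
standard error $\sqrt{p(1-p)/R}$), mean estimate, CI width and coverage.
Replicate $r$ uses a seed substream drawn once from the master seed, so
every method sees identical data and runs are reproducible. The mixed
analysis includes a sample-level intercept only when the layout has
genuine replication below the sample (otherwise $\sigma_S$ and
$\sigma_\varepsilon$ are confounded and the subject-only model is fitted).
The default study grid shipped in `inst/extdata/sim_study.yaml` spans
ICC 0 to 0.5 and cluster sizes 5 to 20 at 20 subjects per group — sizes at
which the asymptotic approximation to the naive test's rejection rate,
$2\Phi(-z_{\alpha/2}/\sqrt{\mathrm{VIF}})$, is accurate and which a
laboratory two-group comparison could realistically field. Test and
acceptance runs use 100–2000 replicates depending on the property being
measured: equivalence checks need few replicates, operating-characteristic
comparisons against the analytic approximation use 2000 (Monte-Carlo SE
about 0.011 on a rate of 0.55), and the variance-component recovery study
uses 500 replicates of the 12-subject, 2-sample, 3-replicate layout with
$\sigma = (0.4, 0.2, 0.1)$. Recovery is asserted on the variance scale,
where REML's unbiasedness property lives; on the SD scale Jensen's
inequality necessarily pulls $E[\hat\sigma]$ slightly below $\sigma$ in
small samples, which is a property of the estimand transform, not an
estimator defect.

## Known limitations

* Crossed random effects, heteroscedastic residuals, autocorrelated
  repeated measures, and outcome transformations are out of scope.
* The binomial model supports a subject-level intercept only (no
  sample-level random effects), a logit link, and no MCMC alternative.
* Containment df is conservative for unbalanced designs; users needing
  Satterthwaite-type df should use a dedicated mixed-model package.
* The power calculators are Gaussian-only; binomial power requires the
  simulation engine plus a user-supplied analysis wrapper.
* Wald intervals for variance components can be poor near the boundary;
  they are suppressed (`NA`) rather than reported there.
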