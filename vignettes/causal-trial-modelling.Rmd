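---
title: "Causal path modelling of a neuroprotection trial: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal path modelling of a neuroprotection trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtrial)
```

# The problem

A phase-2 trial of simvastatin in secondary progressive multiple sclerosis
found beneficial effects on brain atrophy (SIENA percentage brain volume
change, PBVC), disability (EDSS) and patient-reported physical impact
(MSIS-29v2). Statins lower serum cholesterol, but they also have
pleiotropic effects. An arm-comparison analysis cannot distinguish the two
mechanisms. `pathtrial` frames the question as a comparison of two
structural hypotheses over *annualized changes* — per-subject
`(year-2 − baseline)/2` for every outcome:

* **Model A (cholesterol-mediated)**: treatment acts only on serum
  cholesterol; cholesterol change drives atrophy and the clinical cascade.
* **Model B (cholesterol-independent)**: treatment acts directly on every
  outcome; cholesterol change is a disconnected consequence.

In both, atrophy drives EDSS, block-design cognition and MSIS, and EDSS
and block design drive MSIS, which closes the cascade as the terminal
patient-reported outcome.

# The path model and its estimation

A path model over observed variables $y$ is the recursive linear system
$y = \alpha^* + B y + \varepsilon$, with treatment exogenous (free mean
and variance) and independent normal residuals per endogenous equation
(diagonal $\Psi$). The implied moments are
$\mu = (I-B)^{-1}\alpha^*$ and $\Sigma = (I-B)^{-1}\Psi^*(I-B)^{-T}$.

Estimation is by **full-information maximum likelihood**: each subject
contributes the log-density of whatever subset of variables they have
observed, under the implied moments marginalized to that subset. This uses
every partially observed row without imputation, and is valid under
missing-at-random dropout. Rows with nothing observed are dropped and
counted. Internally rows are grouped by missingness pattern and
represented by count, mean and scatter, so a likelihood evaluation costs
the same for 100 or 100,000 complete rows.

Numerical choices:

* Optimizer: L-BFGS-B over the packed parameter vector (exogenous means,
  exogenous covariance Cholesky with log diagonal, intercepts, edge
  coefficients, log residual SDs), from OLS-on-complete-cases starting
  values, with up to 3 jittered restarts. Log-scale parameters are bounded
  below at −12 so that a degenerate (zero-residual) equation lands on the
  boundary with a finite likelihood instead of diverging.
* Convergence: optimizer success plus a scaled projected-gradient norm
  below $10^{-5}$; at an active variance boundary the finite-difference
  gradient is meaningless (curvature $\sim 1/\psi^2$), so the optimizer's
  verdict stands there.
* On complete data, the FIML maximum coincides with per-equation least
  squares for a recursive system with diagonal $\Psi$; the test-suite
  exploits this as an independent oracle (tolerance $10^{-6}$) over random
  DAGs.

**Robust standard errors** are the plain Huber–White sandwich
$A^{-1}(\sum_i g_i g_i^T)A^{-1}$, with the observed information $A$ and
per-row scores $g_i$ obtained by central finite differences. No scaled
test statistic is computed — the reference analysis reports robust SEs
only. EDSS, an ordinal 0–10 scale in half-point steps, is deliberately
treated as continuous with robust SEs rather than through an ordinal
link; this mirrors the reference analysis and is a documented limitation.

**Fit indices.** $T = 2(\ell_{sat}-\ell_M)$ with
$df = p(p+3)/2 - k$ (mean structure included). The saturated model is
fitted as a complete recursive system — which reproduces any mean and
positive-definite covariance — and the baseline as the edge-free system
(uncorrelated variables), so both are well defined under missing data.
CFI uses the standard noncentrality form; RMSEA uses $N$ (not $N-1$) in
the denominator, with a 90% CI by noncentral-$\chi^2$ inversion — the
standard method, noted explicitly because software conventions differ.
SRMR is the root-mean-square of correlation-scale covariance residuals
over unique elements only (no mean residuals), with the saturated-model
implied covariance standing in for the sample covariance so the
definition survives missing data.

# Model comparison

Akaike and Schwarz weights $w_m \propto \exp(-\Delta_m/2)$ are computed
on the log scale (stable for $\Delta$ in the hundreds); evidence ratios
are weight ratios. Bootstrap distributions of CFI/SRMR/RMSEA/AIC/BIC use
**case resampling of subjects** — subjects are the exchangeable unit in a
randomized trial; residual resampling would presuppose the model being
assessed. Percentile 95% intervals are reported (not BCa), matching the
plain intervals of the reference analysis; non-converged replicates are
dropped and counted, with more than 10% failures escalated to an error.

# Bayesian mediation

Each mediation model has exactly three variables — treatment, mediator,
outcome — as two regressions: $m = \alpha_1 + a\,t$ and
$y = \alpha_2 + c't + b\,m$. Indirect effect $= a\cdot b$, total
$= a\cdot b + c'$. Sampling is by a **Gibbs sampler with conjugate
normal–inverse-gamma full conditionals**, which is exact for this
linear-normal model and dependency-free; a general-purpose HMC sampler
would add machinery without changing the posterior. "Noninformative
uniform priors" are realized as flat priors on coefficients and a uniform
prior on the log residual SD in [−10, 10] (recorded in the output; the
bounds never bind in practice). Defaults are 4 chains, 4,000 burn-in and
10,000 retained draws pooled across chains; split-$\hat R \ge 1.01$ flags
the result rather than erroring. Under these priors the marginal
posterior of each coefficient is a location-scale $t$ centred at OLS,
which the tests use as an analytic oracle.

Two proportion-mediated summaries are emitted because the arithmetic
behind a single printed percentage is not identifiable from a report: the
headline is the **ratio of posterior medians** (median indirect / median
total), and the posterior of the per-draw ratio is reported alongside.
When the posterior median total effect is within $10^{-8}$ of zero the
proportion is flagged undefined. Significance throughout is the 95%
credible interval excludes-zero rule. This stage uses listwise deletion
on its three variables (logged); extending FIML into the Bayesian stage
is out of scope.

# Mixed-effects screening and regional analysis

Variable screening fits, per candidate outcome,
`outcome ~ time * arm + (1 + time | subject)` by **maximum likelihood**
(not REML, so likelihoods are comparable across fixed-effect structures —
the reference analysis does not say which it used) and selects outcomes
whose arm-by-time Wald $p$ (normal reference) falls below $\alpha$. The
default $\alpha = 0.05$ is configurable; the reference analysis describes
"significant (or marginally significant)" selection without a numeric
rule, so the threshold is an explicit package choice. Singular
random-slope fits fall back to a random intercept, flagged.

The regional stage fits the same model per region with volume as outcome
and age, sex, center, scanner and total intracranial volume as
covariates. Rates convert to %/year against the **cohort mean baseline
volume** (the denominator is not defined in the reference analysis; a
per-subject-baseline alternative sits behind a flag). The combined-arms
slope tests are BH-FDR-adjusted across regions; the arm-difference
p-value is reported unadjusted, as in the reference analysis. Arm-specific
rates come from a single model with arm-specific slope parameterization
rather than two within-arm refits — one model, one residual variance; the
alternative reading of the reference text is noted. The medulla oblongata
(a spinal-cord proxy) is an ordinary region in the generator's table, not
a special case.

# What the generator emulates — and what it does not

The generator's defaults *are* the stated world of the analysis:

* Two arms, three annual visits (0, 1, 2 years); 70 subjects/arm by
  default. The analyzed n of the original trial is never printed, so
  70/arm (a phase-2 scale) is a configuration choice, not a fact.
* Latent annual rates per subject drawn equation-by-equation from the
  structural model in topological order; visit value = baseline +
  rate × time + measurement noise. Coefficients are unstandardized
  effects on annualized-change scales; the three published treatment
  paths (−0.739 cholesterol, 0.234 PBVC, −0.086 EDSS) anchor the default
  model-B coefficients, and the rest are synthetic stand-ins with
  field-plausible signs, labelled as such.
* Residual SDs for cholesterol (0.45), PBVC (0.55) and EDSS (0.25) are
  back-computed from the published coefficient SEs at the trial's scale
  (SE·√n/2 at n ≈ 140); the others are plausible one-off choices.
* EDSS non-normality is implemented as rounding of a continuous latent to
  0.5 steps within [0, 10] — the reference analysis says only that EDSS
  is non-normal.
* Visit-level measurement noise defaults are small relative to each
  scale (e.g. 0.2 mmol/L cholesterol, 0.1% PBVC): enough that
  per-subject trajectories are not exactly linear (mixed models need a
  residual), small enough that attenuation of paths through the measured
  mediator is negligible (<1%). Passing `measurement_sds = 0` gives the
  exact noise-free limit used by the machine-precision tests.
* Regional volumes change linearly at configured %/year of baseline with
  a shared subject-level atrophy factor; the anchored rates are lateral
  ventricles +1.95, transverse temporal −1.58 placebo / −0.79 treated,
  thalamus −0.24, medulla 0. Regional covariance beyond the shared factor
  is not modelled — the reference analysis does not describe it.
* Missingness: MCAR cell-level or MAR visit-level dropout driven
  logistically by baseline EDSS, intercept-calibrated to the requested
  overall rate.

A green test on this world therefore establishes that the *estimators*
are correct and calibrated, not that real trial data meet the model's
assumptions (no scanner drift, no informative dropout, no floor/ceiling
effects — the frontal assessment battery's ceiling is exactly why such a
variable fails screening in real data).

# Degenerate inputs and tie-breaks

Cyclic structural specs are rejected by name at validation; duplicate
edges and edges into exogenous variables likewise. A saturated spec
(df ≤ 0) reports CFI = 1, RMSEA = 0, flagged. Zero-variance regions are
skipped with a log entry. Ties in the topological sort break by declared
variable order, making evaluation order (and hence generation under a
fixed seed) deterministic. All stochastic stages consume integer seeds;
the pipeline derives stage seeds from one global seed by fixed offsets.

# Known limitations

No latent variables, no ordinal-probit EDSS, no multi-group models, no
Satorra–Bentler scaled statistics, no small-sample AICc, no sensitivity
analysis for unmeasured confounding, no multi-mediator models, and no
imaging: regional volumes enter as numbers. The acceptance checks run on
synthetic data generated from published coefficients — parameter
*recovery*, not reproduction of restricted trial data.
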