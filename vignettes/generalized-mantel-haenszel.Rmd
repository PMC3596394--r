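---
title: "Model-based generalization of the Mantel-Haenszel odds ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based generalization of the Mantel-Haenszel odds ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genmh)
```

## The estimation problem

Two dichotomous variables $X$ and $Y$ are observed on $n$ subjects
together with an $m$-dimensional covariate vector $Z$, in a design — such
as a cross-sectional survey — where neither variable is the natural
dependent one. The target is the odds ratio
$\psi = \dfrac{P(1,1)\,P(0,0)}{P(1,0)\,P(0,1)}$ between $X$ and $Y$ at
fixed $Z$, summarised over the population, using an estimator that is
symmetrical in $X$ and $Y$.

The classical Mantel-Haenszel (MH) estimator pools 2×2 tables over
discrete strata of $Z$,
$$\hat\psi_{MH} = \frac{\sum_i n_{11i} n_{00i}/n_i}
                       {\sum_i n_{10i} n_{01i}/n_i},$$
and is symmetrical, but requires exact matching on $Z$: strata in which
any margin is zero contribute nothing, so with continuous $Z$ the
estimator degenerates. Writing the stratum counts as within-stratum
fractions and replacing those fractions with *model-based* subject-level
classification probabilities $p_{xyi} = P(X=x, Y=y \mid Z = z_i)$ yields
the generalized estimator implemented here,
$$\hat\psi_{gMH} = \frac{\sum_i p_{11i}\, p_{00i}}
                        {\sum_i p_{10i}\, p_{01i}},$$
with the sum over subjects. It is a weighted mean of the subject-specific
odds ratios $p_{11i}p_{00i}/(p_{10i}p_{01i})$ and therefore always lies
between their minimum and maximum.

## The joint multinomial logistic model

The classification probabilities come from a four-category multinomial
logistic model for the joint outcome $(X, Y)$,
$$P(X = x, Y = y \mid Z = z) \propto \exp(\alpha_{xy} + \beta_{xy}^T z),$$
with category $(0,0)$ as the reference ($\alpha_{00} = 0$,
$\beta_{00} = 0$), so there are $3$ intercepts and $3m$ slopes. The model
treats $X$ and $Y$ jointly and symmetrically: relabelling
$(X,Y) \to (Y,X)$ merely swaps the $(0,1)$ and $(1,0)$ categories, and
every downstream estimate is invariant (this is verified end-to-end in
the test suite).

Under this model the subject-specific log odds ratio is affine in $z$:
$$\eta_i = (\alpha_{11} - \alpha_{10} - \alpha_{01})
         + (\beta_{11} - \beta_{10} - \beta_{01})^T z_i .$$
The *homogeneity* hypothesis — the odds ratio does not depend on $Z$,
which is the situation in which a single summary odds ratio is most
meaningful — is therefore the linear hypothesis
$\delta = \beta_{11} - \beta_{01} - \beta_{10} = 0$. Under homogeneity
the common log odds ratio is the intercept contrast
$\log\psi = \alpha_{11} - \alpha_{10} - \alpha_{01}$, and its constrained
ML estimate coincides exactly with $\hat\psi_{gMH}$ computed from the
constrained-fit probabilities; with a single categorical $Z$ and a
saturated fit, $\hat\psi_{gMH}$ coincides exactly with the classical MH
estimator. Both identities are enforced numerically in the acceptance
tests (relative error below $10^{-6}$ and $10^{-8}$ respectively).

### Relationship to binary logistic regression

The joint model implies a binary logistic model for each conditional
distribution. For $Y$ given $(X, Z)$ the implied coefficients are
$\gamma_0 = \alpha_{01}$, $\gamma_1 = \alpha_{11}-\alpha_{10}-\alpha_{01}$,
$\gamma_2 = \beta_{01}$ and $\gamma_3 = \delta$: homogeneity is exactly
the absence of exposure-covariate interaction in the conditional model,
and $\gamma_1$ is the same parameter $\log\psi$. The directly fitted
binary logistic regression maximizes a different (conditional)
likelihood, so its estimate differs from the joint-model estimate in
finite samples; the gap shrinks at the usual $n^{-1/2}$ rate, which the
test suite checks on a ladder $n \in \{500,\ 5000,\ 50000\}$.
`fit_binary_logistic()` exposes both directions, and `mh_report()` prints
them beside the symmetrical estimates — their closeness is itself an
informal indicator of approximate homogeneity.

## Fitting: algorithm and numerical choices

The log-likelihood of the multinomial logistic model is concave, which
makes the optimisation routine straightforward:

* **Newton-Raphson on the observed information** with step-halving,
  started from zero (uniform category probabilities). Concavity makes the
  starting point uncritical; five to seven iterations typically suffice.
* **Convergence** requires both a relative log-likelihood change below
  `1e-10` and a gradient max-norm below `1e-8`, capped at 200 iterations.
  These tolerances are this package's choice; they put the fitted optimum
  well inside the `1e-6` agreement demanded of it by the independent
  optimizer cross-checks.
* **Constrained fits** impose $\beta_{11} = \beta_{01} + \beta_{10}$ by
  reparameterization: the free vector is
  $(\alpha_{01}, \beta_{01}, \alpha_{10}, \beta_{10}, \alpha_{11})$ of
  length $3 + 2m$, and all derivatives are mapped through the (constant)
  Jacobian $A$ of the constraint embedding. The reported covariance is
  always expanded back to the full $3(m+1)$-parameter space as
  $A \Sigma_{free} A^T$, so delta-method code downstream does not need to
  know which fit produced it.
* **Softmax computations** subtract the row maximum before
  exponentiation, so large linear predictors cannot overflow.
* **Separation** is declared when any parameter exceeds 30 on the
  linear-predictor scale (odds factors beyond $e^{30}$ are
  indistinguishable from a perfectly classified category); the fit stops
  with an error that suggests reducing covariates rather than silently
  returning boundary estimates. No penalization is applied, keeping the
  estimates plain ML.
* **Degenerate inputs**: a dataset missing one of the four $(x,y)$ cells
  is rejected up front (the corresponding intercept would diverge);
  $m = 0$ is fully supported and reproduces the crude-OR closed forms.

## Inference

The standard error of $\log\hat\psi_{gMH}$ is obtained by the delta
method: the gradient of
$\log\left(\sum_i p_{11i}p_{00i}\right) - \log\left(\sum_i p_{10i}p_{01i}\right)$
with respect to the model parameters is computed analytically through the
softmax (using
$\partial p_c/\partial \eta_k = p_c(\mathbb{1}[c=k] - p_k)$), and
sandwiched with the ML covariance. A central finite-difference gradient
(step $10^{-6}$) is kept as a verification path and is compared to the
analytic gradient in the tests (max absolute difference below $10^{-5}$);
a nonparametric bootstrap (`bootstrap_se()`) provides a further
model-free cross-check, with bootstrap/delta ratios required to stay
within 10% in the acceptance suite. On an $m=0$ saturated fit the delta
method reproduces the textbook crude-OR variance
$1/n_{00}+1/n_{01}+1/n_{10}+1/n_{11}$ exactly, which the tests assert.

Homogeneity is tested two ways, both against a $\chi^2_m$ reference with
no small-sample correction: a Wald statistic
$\hat\delta^T V_{\hat\delta}^{-1} \hat\delta$ from the unconstrained fit,
and a likelihood-ratio statistic $2(\ell_u - \ell_c)$ from the nested
pair. Tiny negative LR values (within $10^{-6}$) are clamped to zero;
anything more negative signals an optimizer failure and raises an error.
With $m = 0$ the hypothesis is vacuous and both tests return $p = 1$ by
convention.

Confidence intervals are always computed on the log scale,
$\exp(\log\hat\psi \pm z_{1-\alpha/2}\,\widehat{se})$, and reported on
the OR scale.

### Choices where the method itself is silent

* The classical MH column carries the Robins-Breslow-Greenland variance —
  the standard companion of the MH point estimate — so that every row of
  the estimator table has a usable standard error.
* The average-of-$\eta_i$ estimator is reported with a delta-method SE
  whose gradient is the average of the (exactly linear) per-subject
  gradients.
* When the classical MH numerator or denominator sum is zero the log OR
  is reported as $\pm\infty$ with a missing SE, keeping the two
  degenerate directions distinguishable without raising an error.
* Complete-case handling: rows missing any selected column are dropped
  with a reported count; no imputation, no automated screening of
  implausible values (no defensible general rule exists — screening is
  left to the analyst).
* Categorical covariates use reference-cell (dummy) coding with a
  configurable reference level, matching standard epidemiological
  practice; continuous covariates are left on their raw scale by default
  because the estimators are invariant to affine covariate rescaling at
  the optimum (tested), while raw coefficients stay interpretable.

## The simulator and what the tests do (and do not) show

`simulate_mh_data()` draws covariates i.i.d. from per-column laws
(normal, Bernoulli, uniform — enough to emulate an age-type continuous
confounder, binary group indicators, and dummy-coded ordinal groups),
computes the four category probabilities from the same parameterization
the fitter uses, and samples one category per subject.
`simulate_stratified()` generates the discrete-strata design in which the
classical-MH identity holds. `run_mh_study()` spawns one sub-seed per
replicate from a master seed, so studies are reproducible and replicates
independent; replicate-level fit failures are caught and counted rather
than fatal.

The default validation conditions, chosen once as representative of a
moderate epidemiological study, are: homogeneous truth with common odds
ratio 2 ($\alpha = (0.25, -0.125, \log 2 + 0.125)$, slope columns
$(0.5, 0.25, 0.75)$ and $(0.25, 0.125, 0.375)$ — each third entry the sum
of the first two, so $\delta = 0$ holds exactly in floating point), one
standard-normal and one Bernoulli(0.4) covariate. The validation suite
uses $n = 2000$ with 500 replicates for bias and coverage, $n = 500$ with
1000 replicates for test size, $n = 2000$ with 500 bootstrap replicates
for the SE cross-check, and ten $n = 200$ datasets for the
independent-optimizer comparison; asymptotic-agreement properties (Wald
vs LR, joint vs conditional fits) are checked at larger $n$ where the
asymptotics are expected to have set in.

Because generator and fitter share one model family, these simulations
demonstrate *internal* correctness — identities, unbiasedness, nominal
coverage and size *under a correctly specified model*. They do not
address misspecification of the multinomial logistic form, informative
sampling designs (survey weights are out of scope), measurement error,
or real-data artefacts such as implausible recorded values. Passing
tests therefore certify the machinery, not the adequacy of the model for
any particular dataset.

## Recommended workflow and limitations

`mh_report()` follows the workflow the method suggests: fit the joint
model, test homogeneity, and — if homogeneity is not rejected (default
$\alpha = 0.05$) — report the constrained ML estimate as the adjusted,
symmetrical odds ratio. Under apparent heterogeneity a single summary OR
is not meaningful; the report then surfaces the distribution of the
subject-specific log odds ratios (`subject_log_or()`,
`autoplot(<fit>)`) for exploration against the covariates.

Known limitations: plain ML only (no regularization, no Bayesian fit);
no survey weights; no matched-pair sparse-strata asymptotics (the
delta-method variance is a large-strata result); no exact conditional
inference or continuity corrections for the classical MH column; and no
goodness-of-fit machinery for the multinomial logistic model itself —
adjustment through a badly misspecified model can mislead, as can
adjustment for variables that are not actually confounders.
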