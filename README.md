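# genmh

Symmetrical covariate-adjusted odds ratios via a generalized
Mantel–Haenszel procedure.

## The problem

Epidemiologists routinely need the residual association between two
dichotomous variables X and Y (say, smoking and a persistent viral
infection) after adjusting for confounders Z (age, sex, behaviour, …).
The two standard tools each have a defect for this task:

* **Binary logistic regression** (Y on X and Z, or X on Y and Z) is not
  symmetrical in X and Y — the two directions generally give different
  adjusted odds ratios and standard errors, which is awkward when neither
  variable is the natural "outcome".
* The **classical Mantel–Haenszel (MH) estimator** is symmetrical, but it
  only works when Z defines a limited number of discrete strata: with a
  continuous or high-dimensional Z, strata become unique to subjects and
  every observation is discarded.

`genmh` implements a model-based extension of the MH estimator to
continuous and vector-valued Z that keeps its symmetry.

## The method

Writing `n_xyi` for the cell counts of the 2×2 table in stratum *i*, the
classical MH estimate

```
OR_MH = Σ_i (n11_i n00_i / n_i) / Σ_i (n10_i n01_i / n_i)
```

can be rewritten in terms of observed within-stratum fractions `p_xyi`.
Replacing those fractions with *subject-specific classification
probabilities* `p_xyi = P(X = x, Y = y | Z = z_i)` from a model gives the
generalized estimator (the sum now runs over subjects):

```
OR_gMH = Σ_i p11_i p00_i / Σ_i p10_i p01_i
```

The probabilities come from a four-category **multinomial logistic model**
for the joint (X, Y) distribution, with category (0,0) as reference:

```
P(X = x, Y = y | Z = z) ∝ exp(α_xy + β_xyᵀ z),   α_00 = 0, β_00 = 0
```

This model is symmetrical in X and Y by construction. The subject-specific
log odds ratio is

```
η_i = (α_11 − α_10 − α_01) + (β_11 − β_10 − β_01)ᵀ z_i
```

so the odds ratio is constant in Z (homogeneity) exactly when
`δ = β_11 − β_01 − β_10 = 0`. Under that constraint the common log odds
ratio is the simple intercept contrast `log ψ = α_11 − α_10 − α_01`,
estimated by constrained maximum likelihood — and this constrained ML
estimate is *identical* to OR_gMH computed from the homogeneity-model
probabilities. When Z is a single categorical variable, the saturated fit
makes OR_gMH identical to the classical MH estimator, recovering the
textbook procedure as a special case.

The package provides:

* `fit_mh_multinomial()` — Newton–Raphson ML fit of the joint model,
  unconstrained or under the δ = 0 reparameterization;
* `or_generalized_mh()`, `or_constrained_ml()`, `or_classical_mh()`,
  `or_crude()`, `or_avg_subject()`, `subject_log_or()` — the estimators,
  each returned as a tidy one-row tibble with delta-method standard
  errors and 95% confidence intervals;
* `test_homogeneity()` — Wald and likelihood-ratio tests of δ = 0;
* `bootstrap_se()` — nonparametric bootstrap cross-check of the
  delta-method standard errors;
* `fit_binary_logistic()`, `gamma_from_multinomial()` — the two
  asymmetrical logistic fits and the algebraic map linking them to the
  joint model;
* `simulate_mh_data()`, `simulate_stratified()`, `run_mh_study()` — a
  simulator in the model's own parameterization for recovery, coverage
  and type-I-error studies;
* `mh_report()` — the whole workflow in one call, with `tidy()`,
  `glance()` and `autoplot()` methods;
* `inst/cli/genmh.R` — a small command-line wrapper
  (`estimate`, `simulate` subcommands).

## Worked example

Simulate 1,500 subjects from the joint model with a common odds ratio of
2 (δ = 0), confounded by a continuous and a binary covariate, and run the
full analysis:

```r
library(genmh)

sim <- simulate_mh_data(
  1500,
  alpha = c(0.25, -0.125, log(2) + 0.125),
  beta  = matrix(c(0.05, 0.025, 0.075, 0.25, 0.125, 0.375), 3, 2),
  covariates = list(age = cov_normal(45, 10), male = cov_bernoulli(0.45)),
  seed = 42)
names(sim) <- c("smoker", "hsv2", "age", "male")

report <- mh_report(sim, x = "smoker", y = "hsv2", z = c("age", "male"))
report
```

```
Symmetrical adjusted odds-ratio analysis
  n = 1500, design columns m = 2

            estimator   or ci_low ci_high se_log_or    n
                crude 2.27   1.34    3.83     0.267 1500
       generalized_mh 2.12   1.25    3.60     0.270 1500
 avg_subject_specific 2.01   1.11    3.63     0.302 1500
       constrained_ml 2.11   1.25    3.59     0.270 1500
      logistic_y_on_x 2.12   1.25    3.60     0.270 1500
      logistic_x_on_y 2.11   1.24    3.59     0.270 1500

Homogeneity of the odds ratio (H0: delta = 0):
 method statistic df p_value
   wald      0.17  2   0.919
     lr      0.17  2   0.919

Recommended estimate: constrained_ml
```

Reading the output: the crude odds ratio (2.27) overstates the
association because both variables depend on the covariates; every
adjusted estimator lands near the generating value of 2. The homogeneity
tests give no evidence that the odds ratio varies with the covariates
(p = 0.92), so the report recommends the constrained ML estimate — here
2.11 (95% CI 1.25–3.59), agreeing with the generalized MH estimate to
two decimals, as the underlying identity guarantees. The two asymmetrical
logistic estimates are close to, but not exactly equal to, the
symmetrical ones, because their likelihoods differ.

`tidy(report)` returns the estimator table as a tibble, `glance(report)`
a one-row summary, and `autoplot(report)` a forest plot.

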