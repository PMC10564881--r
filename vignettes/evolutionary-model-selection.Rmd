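---
title: "Evolutionary model selection with a BIC fitness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary model selection with a BIC fitness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the optimization
model and its assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The optimization model

`run_iel()` searches the product space of hyperparameter assignments and
feature subsets with a genetic algorithm. One candidate — a *chromosome* —
is a pair (hyperparameter vector over a declared search space, index list of
2 to 50 features drawn from the candidate pool). Fitness is the Bayes
Information Criterion

$$\mathrm{BIC} = p\,\ln n - 2\,\ln L,$$

with $p$ the number of *selected features*, $n$ the number of
cross-validation-scored observations, and $\ln L$ the summed out-of-fold
binomial log-likelihood (nats, probabilities floored at $10^{-12}$).

Two ingredients deserve justification because the classical BIC is defined
for likelihood models with a parameter count:

* **Complexity term = selected features.** Boosted trees and neural
  networks have no meaningful parameter count at this granularity, and the
  quantity the search actually spends is features. Charging $p\,\ln n$ per
  feature makes fitness comparable across the three families and directly
  penalizes what the optimizer can inflate. `parameter_count()` is reported
  for reference but never enters the fitness.
* **Likelihood = out-of-fold.** An in-sample likelihood would reward
  overfitting before the complexity term could react; the cross-validated
  likelihood estimates generalization at the same $n$ for every candidate.

### Generation bookkeeping

At the reference population of 100 models per generation: rank by BIC; of
the best 80, the top 40 are recombined in adjacent-rank pairs into 20
children, the next 20 are mutated into 20 more children, and 20 are
discarded; 60 fresh random models complete the next generation. Feature
sets are not crossed over: the 40 children receive, in rank order, the
feature subsets of the best 60 models (surplus donors are discarded). Any
other population size scales these proportions (population 20 → 4
recombined + 4 mutated + 12 fresh, best 16 kept). Evolution stops when the
best-so-far BIC improves by less than `plateau_tol` (0.1% relative) over
`plateau_window` generations.

Recombination averages hyperparameters after a midpoint pivot (copy from
the first parent before it); the average is geometric for log-scaled genes
and a seeded coin flip for categorical ones. Mutation shifts one gene by
its declared mutation shift (default 10% of the bound width, log-space for
log-scaled genes) and reflects at the bounds.

### Warm restart and recursive learning

After the plateau the search is *warm-restarted* on a restricted pool:
permutation importances (5 repeats, AUC scoring) are aggregated over the 60
best models refit on the full training partition, the
fitness-versus-feature-count curve is reduced to its elbow, and the pool is
cut at the importance of the elbow-ranked feature. Post-restart generations
shrink to half the population with a 40%/20%/40% recombined/mutated/fresh
split (50 → 20/10/20).

Three design choices here departed from our first implementation after it
demonstrably failed at small scale, and are worth recording:

1. **Convex-corner elbow.** The elbow is the point of maximum
   *signed* perpendicular distance below the chord of the normalized curve.
   The unsigned variant selects arbitrary bumps on noisy, unconverged
   curves.
2. **Scree bound on the pool.** On short runs the fitness curve has not
   explored small subsets well and its elbow overshoots (we observed counts
   of 16–36 on a 40-feature pool). The pool is therefore additionally
   bounded by the elbow of the sorted importance profile — features beyond
   the scree corner have no appreciable measured importance, so a threshold
   "by importance" cannot meaningfully include them.
3. **Recursion.** The restrict–rerun cycle is applied repeatedly (up to
   `warm_recursions = 4` rounds, stopping when the pool no longer shrinks)
   before the escalating cutoffs. A single restriction step leaves no
   intermediate rung between a ~16-feature pool and the 2–3 features that
   survive a mean + 2 SD cut; recursion supplies the ladder.

After recursion, learning repeats on pools thresholded at mean + m·SD of
the aggregated importance for m = 2..10, stopping when a cutoff leaves
fewer than two features.

### Cross-validation

The fold count adapts to model complexity: $k$ is the nearest integer
strictly above $n/p$ (integer ratios round up by one), stratified by label,
capped at `cv_cap = 10` by default — uncapped, a 2-feature model on 784
subjects would demand 393 folds, which buys nothing statistically and is
computationally absurd. If $k$ exceeds the minority class count it falls
back to that count so each fold can contain both classes. Fold assignment
is seeded independently of the chromosome, so two candidates with the same
subset size face identical folds and their BICs are exactly comparable.

## Estimator families

* **Elastic-net logistic regression** (`glmnet`): search over the mixing
  parameter in [0, 1] and penalty strength, log-uniform in
  [10⁻³, 10³].
* **Gradient-boosted trees** (`xgboost`, gbtree booster): learning rate
  [0.01, 0.5], depth [2, 10], rounds [50, 500], subsampling and column
  sampling [0.5, 1], L2 penalty [0, 10], split gain [0, 5].
* **Multilayer perceptron** (native implementation: no deep-learning
  framework is a package dependency): fixed architecture of three hidden
  layers of 300 ReLU units with a 2-unit softmax output, Adam updates,
  early stopping with patience 3 on the validation loss of a seeded 10%
  split of each training fold; searched over log-uniform learning rate
  [10⁻⁵, 10⁻¹], batch size [16, 256] and epochs [10, 200].

The non-logistic ranges are this package's defaults, chosen generously for
exploration; they are not canonical values. All three families satisfy one
contract — `fit_estimator()`, `predict_proba()`, `parameter_count()`,
`inherent_importance()` — so the optimizer is family-blind. Inherent
importance is |coefficient| for the logistic family and gain for trees; the
MLP returns `NULL` and is explained by permutation only.

## The preparation pipeline

`prep_fit()` learns, in fixed order, on the training partition only:

1. **Sparse-feature drop** — features with *strictly more* than 40%
   missing cells are discarded.
2. **Outlier trim** — observed values clipped to mean ± 3 SD. Trim bounds
   are a per-partition operation (each partition is trimmed against its own
   moments); everything below is a fitted parameter applied unchanged to
   test data.
3. **Masked NNMF imputation** — values are shifted non-negative, a
   rank-`nnmf_rank` (default 10) factorization is fitted by multiplicative
   updates minimizing squared error over *observed* cells only
   (`tol = 1e-5` relative, `max_iter = 500`), and only missing cells are
   replaced; observed entries are returned bit-identical. Test partitions
   are imputed against the frozen feature basis by refitting subject
   factors only.
4. **Min–max scaling** — train minimum to 0, maximum to 1; test values may
   fall outside [0, 1] and are not clipped.
5. **Normalizing-transform selection** — each feature is compared
   untransformed, Yeo-Johnson power-transformed (maximum-likelihood
   lambda), and rank-mapped to normal scores, by the Anderson–Darling
   statistic. A column that already passes Anderson–Darling normality at
   α = 0.05 stays untransformed. This gate is deliberate: a rank-based
   quantile map is essentially always the statistic's minimizer, so a pure
   minimization rule would transform everything, including
   already-Gaussian features — the gate restricts transformation to
   features with evidence of non-normality. Exact ties break
   none → power → quantile.

Feature agglomeration (`agglomerate_items()`) merges related columns by
Ward linkage on Euclidean column distance and pools the final cluster as
the leaf mean; targets built from symptom items (`binarize_target()`) label
exactly-zero agglomerated scores as not-case. `resample_smoteenn()`
oversamples the minority class to parity by interpolating between a
minority row and one of its k = 5 nearest minority neighbours, then applies
edited-nearest-neighbour cleaning (k = 3, majority vote over both classes);
it is only ever applied to training data, and the class ratio may
legitimately overshoot balance.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical shape of a multidomain
community cohort: a rank-`latent_rank` Gaussian latent structure plus
feature noise, pushed through monotone marginal transforms (Gaussian
copula, so dependence and marginal shape are controlled separately);
planted linear, pairwise-interaction and 70th-percentile-threshold effects
on the standardized latent features; labels drawn from a logistic model
whose intercept is calibrated by root-finding to the requested case rate;
MCAR or MAR missingness (MAR: per-block logistic in a fully observed driver
feature). The ground truth records the Bayes-optimal class probabilities
and their empirical AUC — an upper bound no classifier fit to the data
should exceed.

It does **not** emulate real psychometric instruments, item-level
structure, site effects, or realistic cross-domain covariance; passing
tests on it demonstrates that the machinery recovers planted structure
under controlled conditions, not that any particular clinical performance
would be attained on real data. Note one consequence of the logistic link:
labels are Bernoulli draws, so even a noiseless strong effect leaves label
noise — a single linear effect of size 3 yields a generating-score AUC
near 0.91, not 1.

`generate_timecourses()` plants brain-state structure by drawing
consecutive windows of component activity from zero-mean Gaussians with
prescribed correlation-matrix centroids; `cluster_states()` recovers states
by seeded k-means on upper-triangle-vectorized window correlations, and
`dynamic_metrics()` summarizes a state sequence as states traversed,
switches, maximal pairwise L1 span among *visited* centroids ("span" reads
as the extent of the visited set, not consecutive distance), and total L1
distance over switches. Fisher z-values are capped at atanh(0.999999) with
a warning when |r| → 1. Static connectivity is computed on timecourses;
whether spatial-map or temporal correlation is meant in the motivating
setting is ambiguous, and the temporal reading is the one a desk-scale
pipeline can compute.

## Evaluation and explanation

`test_holdout()` refits each retained (hyperparameters, subset) pair on the
full training partition — resampled, if resampling was used — and scores
the untouched test partition at threshold 0.5; no resampling ever touches
test data. AUC is trapezoidal and equals Mann–Whitney concordance with
half-credit ties. `shapley_importance()` uses permutation-sampling Shapley
values whose per-row attributions telescope exactly to
$f(x) - \overline{f(\mathrm{background})}$ (local accuracy is exact by
construction, not asymptotic); when the permutation × background budget
covers the full enumeration it is exact. Odds ratios for the logistic
family come from an unpenalized refit of the selected predictors, because
confidence intervals for penalized coefficients are not well-defined.

## Problem sizes and determinism

The shipped tests and the acceptance script run deliberately small
configurations chosen as representative rather than exhaustive: an
84-configuration fully-enumerable space for oracle comparison; 400-subject,
40-feature cohorts with four planted effects (population 20, 15 main
generations) for recovery; 200 × 30 rank-2 matrices with 20% missingness
for imputation; 10 subjects × 120 windows for brain-state recovery. Every
stochastic component draws from named substreams of one master seed, so
whole runs are exactly reproducible (trees and the logistic family
bit-exactly; the MLP to floating-point reproducibility of its own seeded
training).

## Known limitations

* Feature subsets evolve only by donor reallocation and fresh random
  injection — there is no subset crossover — so subset discovery at small
  budgets leans on the warm-restart machinery; a planted feature whose
  realized association in a given training draw is statistically invisible
  will be dropped by the BIC no matter the search budget.
* The BIC's feature-count complexity term is a design convention, not a
  likelihood-theoretic derivation, for the tree and network families.
* The MLP is plain dense/ReLU with Adam; it makes no claim to match any
  specific deep-learning framework numerically.
* MAR missingness is driven by one observed feature per domain block;
  real nonresponse is richer.
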