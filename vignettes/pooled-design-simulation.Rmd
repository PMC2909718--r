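---
title: "Simulating pooled-sample designs for biosignature classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pooled-sample designs for biosignature classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsim)
```

## The question

Microarray (and other omics) screens sometimes cannot be run on individual
samples: the RNA yield of a single subject may be below the platform minimum,
so RNA extracts of several subjects are mixed — *pooled* — and the pool is
hybridized on one array. Pooling is known to be problematic for
classification studies: once samples are mixed, interindividual variation is
averaged away and multivariate structure may be distorted. poolsim quantifies
this by simulation: it generates two-class expression data with known
discriminating structure, trains classifiers on pooled training sets of
varying pool size, and measures how the prediction error on independent
single samples grows with the pool size, separately for five statistical
learning methods.

## The measurement model

Log2-scale expression of gene $g$ in subject $i$ is modeled as

$$Y_{g,i} = X_{g,i} + \varepsilon_i, \qquad
  X_{g,i} \sim N(\mu_g, \sigma^2), \quad
  \varepsilon \sim N(0, \sigma_\varepsilon^2),$$

with biological variance $\sigma^2$ between subjects and technical
(measurement) variance $\sigma_\varepsilon^2$ per hybridized array. Noise is
independent across genes and arrays; there is no array-wide offset,
normalization artifact, probe effect, or missing-value process — the
generator isolates the pooling effect, it does not emulate raw microarray
data. An ideal pool of size $m_p$ averages the RNA of its members on the
*raw* scale, so the pooled biological value is
$\log_2\!\big(\tfrac{1}{m_p}\sum_{i \in p} 2^{X_{g,i}}\big)$, and one
technical error per pool is added afterwards (one array per pool):
$Y^p_g = X^p_g + \varepsilon_p$. By Jensen's inequality the raw-scale pool is
never below the mean of the member log values; for the small $\sigma$ used
here the pooled biological values are close to
$N(\mu_g, \sigma^2/m_p)$, which `design_variance()` uses for the closed-form
design comparison. (The raw-scale operator and the normal-theory variance
formulas agree only approximately; the data path always uses the raw-scale
operator.) There is deliberately no pooling error beyond the averaging
itself.

## The three scenarios

All scenarios use a $60 \times 1000$ matrix (30 subjects per class A/B) whose
non-informative background is $N(8, 0.2^2)$:

* **DE_ONLY** — ten independent differentially expressed genes: per gene,
  $\mu_A \sim U[6, 10]$, class B shifted by $\Delta \sim U[0.1, 0.5]$
  (1.07- to 1.4-fold changes: deliberately weak single markers).
* **LINEAR_ONLY** — ten bivariate linear patterns: per pattern a first gene
  $g_1$ with a shared class mean, and a second gene
  $g_2 = 2 g_1$ (class A) or $g_2 = 2 g_1 + \delta$ (class B), with
  $\delta = 0.4$. Neither gene is informative alone at realistic power
  ($g_2$ carries a marginal class difference of exactly $\delta$); the
  *pair* is linearly separable.
* **COMBINED** — both blocks.

Informative columns lead the matrix (a `shuffle_columns` flag scatters them
for robustness checks). Technical noise is added to every column — the
measurement model makes no per-column exception — at one of the two study
levels, $\sigma_\varepsilon \in \{0.2, 0.4\}$.

## The evaluation protocol

Each Monte-Carlo repetition draws fresh gene-level parameters
($\mu_A$, $\Delta$, pattern means), a training cohort, and an independent
test cohort of 60 single samples *with the same gene-level parameters* —
training and test describe the same biological classification problem, as
they must for a learned signature to be transferable at all. Training arrays
(singles or pools) carry technical noise at the configured level. Test
singles are evaluated on their biological values (no technical noise) by
default: the benchmark measures how well the learned signature recovers the
true class structure of new subjects. This default reproduces the reference
error levels and degradation ratios of the study this framework models
(for example the roughly 12-fold low-noise and 4-fold high-noise
degradation of t-test+LDA between $m_p = 1$ and $m_p = 5$); a
`test_noise_sd` argument restores fully noisy test measurements, which
raises all error levels and compresses the ratios. Prediction error is the
fraction of misclassified test singles, so it is a multiple of $1/60$.
Pool memberships are re-randomized every repetition; test sets are never
pooled.

## The five classifiers

* **SVML / SVMR** — soft-margin support vector machines (e1071) with linear
  or radial kernel, cost fixed at 1 (the package default; the cost is not
  specified by the study conditions). For SVMR the kernel width $\gamma$ is
  tuned on the grid $2^{-10}, \ldots, 2^{2}$ times $1/p$ by the library's
  internal 10-fold cross-validation, ties toward the smaller $\gamma$.
* **RF** — random forest (randomForest), 1000 trees, 20 candidate variables
  per split.
* **PPLS-DA** — powered partial least squares discriminant analysis,
  implemented in this package (see below).
* **t-test + LDA** — per-gene two-sample pooled-variance $t$-tests (a Welch
  switch exists); the ten smallest $p$-values (ties by column index) select
  the features for a linear discriminant analysis with pooled covariance and
  equal priors. With 12 pooled training arrays and 10 features the pooled
  covariance can be near-singular; a Moore–Penrose pseudo-inverse fallback
  (with a warning) keeps the method defined rather than failing, since poor
  pooled-design LDA results are themselves a finding.

All five share one fit/predict contract (`train_classifier()`,
`predict()`), and within a repetition all methods see the same training and
test data (paired comparison).

### Powered PLS-DA

Per component, each feature's loading weight combines its correlation
$\rho_g$ with the centered class indicator and its standard deviation $s_g$,
tempered by a power parameter $\gamma \in [0, 1]$:

$$w_g(\gamma) \;\propto\; \operatorname{sign}(\rho_g)\,
  \left(\frac{|\rho_g|}{\max_h |\rho_h|}\right)^{\gamma/(1-\gamma)}
  \left(\frac{s_g}{\max_h s_h}\right)^{(1-\gamma)/\gamma}.$$

$\gamma = 0.5$ recovers classic PLS weights (proportional to covariances);
$\gamma \to 1$ concentrates the component on the best-correlated features,
$\gamma \to 0$ on the highest-variance ones; the max-normalization makes the
endpoints well-defined limits (at the endpoints the weight becomes an
indicator of the extreme feature(s)). $\gamma$ is chosen per component on a
fixed 21-point grid over $[0, 1]$ — the grid rather than a continuous
optimizer keeps the choice deterministic and reproducible; at the grid
resolution of 0.05 the objective (squared correlation between the candidate
score $X w$ and the class indicator) is flat enough that finer optimization
does not change the chosen components appreciably. After each component the
predictor matrix is deflated, making successive scores exactly orthogonal.
The number of components (capped at 10 and at $n - 2$) is selected by an
inner stratified 10-fold cross-validation (folds reduced to the smallest
class size when classes are small), minimizing CV misclassifications with
ties resolved toward fewer components; a Fisher linear discriminant with a
midpoint threshold on the discriminant axis classifies the component scores.

## Repetitions, seeding, and summaries

`run_experiment()` crosses scenarios, noise levels, pool sizes, and methods.
Per-repetition seeds are derived by hashing the base seed with the cell
coordinates (`derive_seed()`), so every cell and repetition is reproducible
in isolation and independent of execution order; each method additionally
re-seeds from the repetition seed and its own tag, so a method's result does
not depend on which other methods were run. Summaries report the mean error
per cell with a percentile bootstrap confidence interval for the mean
(1000 resamples, 95% by default — the resample count and the percentile
flavor are this package's choices), plus the degradation ratio of the
largest pool size to the single-sample design. Results can be checkpointed
per cell and resumed.

## Problem sizes and numerical choices

The reference study conditions use 500 repetitions per cell. The package's
own test suite and the bundled acceptance script use smaller repetition
counts chosen so that the Monte-Carlo standard error of a cell mean stays
below about 0.01 (200–500 repetitions for the fast t-test+LDA cells,
roughly 25–120 for the cross-validated SVMR and PPLS-DA cells, with the
largest counts given to the quantities that sit closest to their reference
bounds); at these sizes the reported means are stable to within the
tolerances quoted for them.
Other numerical choices: pool sizes must divide the per-class count (the
study grid 1, 2, 3, 5 divides 30); zero-variance features receive zero
powered-PLS weight (their correlation is undefined); a degenerate power
interval (`lower == upper`) skips the grid search; datasets round-trip
through TSV at 15 significant digits.

## What passing tests do and do not show

The generator emulates the *structure* of a pooled-design classification
study — weak univariate effects, a bivariate pattern that univariate
screening cannot see, raw-scale pooling, per-array noise — under exactly the
idealizations listed above (normality on the log scale, independent noise,
ideal equal-contribution pools, balanced classes). Conclusions transfer to
real arrays only to the extent those idealizations hold; in particular the
absence of pool bias beyond raw-scale averaging, of array effects, and of
normalization artifacts means the simulated degradation is a *lower bound*
of sorts on the trouble pooling can cause. Known limitations: two classes
only, equal class sizes, equal pool sizes, no unequal contribution weights,
and no attempt to reproduce any specific external figure pixel-for-pixel.
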