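# poolsim

Simulation framework for quantifying how RNA **sample pooling** degrades
two-group classification of gene-expression **biosignatures**.

When single samples yield too little RNA, extracts of `m_p` subjects are
mixed and hybridized on one array. poolsim asks what that costs in
classification performance: it simulates two-class log2-scale expression
data with known discriminating structure, pools the *training* samples on
the raw scale, trains five statistical learning methods, and measures the
prediction error on independent single-sample test sets.

## Model

Measured expression of gene *g* on array *i* is

    Y_gi = X_gi + eps_i,   X_gi ~ N(mu_g, sigma^2),  eps ~ N(0, sigma_eps^2)

with biological variance `sigma^2 = 0.2^2` and technical variance
`sigma_eps^2` of `0.2^2` or `0.4^2`. An ideal pool averages its members'
raw-scale values: `Y^p_g = log2(mean(2^X_gi)) + eps_p`, one technical error
per pooled array. Three scenarios place signal in 10 of 1000 features
(plus background `N(8, 0.2^2)`):

* `DE_ONLY` — ten independent differentially expressed genes,
  shift `Delta ~ U[0.1, 0.5]` (weak, 1.07–1.4-fold);
* `LINEAR_ONLY` — ten bivariate linear patterns `g2 = 2*g1 (+ 0.4 in class
  B)`, discriminating as a pair, not univariately;
* `COMBINED` — both.

Classifiers: linear and radial SVM (`e1071`, radial gamma tuned by inner
10-fold CV), random forest (1000 trees, mtry 20), **powered PLS discriminant
analysis** (implemented here: per-component loading weights
`sign(rho) * |rho|^(g/(1-g)) * s^((1-g)/g)` with the power `g` optimized in
[0, 1], component count by inner 10-fold CV, Fisher LDA on the scores), and
t-test feature selection (top 10 p-values) followed by LDA. Mean errors per
(scenario × noise × method × pool size) cell are reported with percentile
bootstrap confidence intervals.

## Worked example

```r
library(poolsim)
cfg <- sim_config(scenario = "DE_ONLY", noise_sd = 0.2)
ex <- run_experiment(scenarios = "DE_ONLY", noise_sds = 0.2,
                     methods = c("svml", "tlda"), pool_sizes = c(1, 2, 5),
                     n_reps = 50, base_seed = 42, cfg = cfg)
set.seed(1)
summary(ex)
#>   scenario noise_sd method m_p mean_error ci_lower ci_upper n_reps degradation
#> 1  DE_ONLY      0.2   svml   1     0.2550   0.2380    0.274     50        1.44
#> 2  DE_ONLY      0.2   svml   2     0.3023   0.2857    0.318     50        1.44
#> 3  DE_ONLY      0.2   svml   5     0.3677   0.3490    0.385     50        1.44
#> 4  DE_ONLY      0.2   tlda   1     0.0387   0.0260    0.052     50        9.63
#> 5  DE_ONLY      0.2   tlda   2     0.1063   0.0833    0.131     50        9.63
#> 6  DE_ONLY      0.2   tlda   5     0.3723   0.3367    0.412     50        9.63
```

Read: with ten weak independent DE genes and low technical noise,
t-test+LDA classifies new single samples almost perfectly when trained on
single samples (4% error) but collapses towards chance when trained on
pools of five (37% — a ~10-fold degradation, the `degradation` column),
while the linear SVM is mediocre but comparatively robust. `plot(ex)` draws
the per-method bar chart with CI whiskers.

Lower-level pieces are exported too: `simulate_dataset()`,
`pooled_training_set()`, `pool_expression()`, `design_variance()`,
`pplsda()` / `train_classifier()` / `predict()`, `bootstrap_ci()`. A small
command line (`inst/cli/poolsim`) wraps simulate / pool / run / summarize
with TSV/CSV/YAML files; see the vignette in `vignettes/` for the methods
account.

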