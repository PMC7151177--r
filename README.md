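# apclass

One-shot associative pattern classification for tabular biomedical data,
with the stratified evaluation protocols used in diagnostic benchmarking.

## The method

The associative pattern classifier (APC) is a hybrid associative memory:
it learns with the Hebbian outer-product rule of the linear associator and
recovers with the maximum-activation rule of the Lernmatrix, applied to
real-valued, mean-translated inputs with one-hot class labels.  Given a
fundamental set of p labeled patterns S = {(x_k, y_k)}, x_k ∈ ℝⁿ,
y_k ∈ {0,1}ᵐ one-hot for the class of x_k:

1. **Learning** (one shot, no iteration):
   - mean vector x̄ = (1/p) Σₖ x_k
   - translated patterns x_tk = x_k − x̄
   - association matrix **M** = Σₖ y_k (x_tk)ᵀ, an m×n matrix whose row j
     is the sum of the translated patterns of class j.
2. **Recovery** for a query x_ω: translate x_tω = x_ω − x̄, score
   z = M x_tω, and assign the class with the strictly maximal component
   of z.

Translation makes the rows of M sum to the zero vector, so for two classes
z₂ = −z₁ always.  The point x_ω = x̄ is the *neutral position*: its
translation is zero, every class scores 0, and the class cannot be found —
the classifier reports it as unclassified (a reject option).  Ties at a
non-zero maximum are likewise rejected by default, or broken to the lowest
class index if you ask.  For balanced two-class data the APC's decision
coincides with the nearest-class-centroid (minimum distance) rule, which
the package also implements natively as a cross-check and baseline.

The package covers the full workflow around the classifier:

- `apc()`, `predict()`, `apc_scores()`, `tidy()`/`glance()`/`autoplot()` —
  fitting, scoring and inspection; `write_apc()`/`read_apc()` for
  plain-text model files.
- `read_wbcd()`/`write_wbcd()` — the Wisconsin Breast Cancer (Original)
  comma-separated dialect (9 cytological features scaled 1–10, `?` for
  missing, class codes 2/4), plus `read_labeled_csv()` for generic labeled
  CSV, with declared missing-value policies (`missing_policy()`).
- `synth_gaussian()`, `wbcd_like_fixture()`, `worked_example()` — seeded
  synthetic data so everything is testable offline.
- `stratified_holdout()`, `stratified_kfold()`, `evaluate_classifier()`,
  `learning_curve()`, `mdc_classifier()`, `baseline_classifier()` — the
  repeated stratified holdout / 10-fold protocols, with rejections counted
  as errors and train-only imputation (no test leakage).
- A command line: `Rscript $(Rscript -e 'cat(system.file("cli","apc.R",package="apclass"))') <train|predict|evaluate|demo|synth> ...`

## Worked example

The two-association fundamental set x¹ = (6,5,2) → class 1,
x² = (−4,11,−8) → class 2 (`worked_example()`):

```r
library(apclass)
fit <- apc(worked_example())
fit
#> Associative pattern classifier: 2 classes, 3 features, 2 patterns
#> Classes: class_1 (1), class_2 (1)
#> Mean vector:
#> f1 f2 f3
#>  1  8 -3
#> Association matrix:
#>         f1 f2 f3
#> class_1  5 -3  5
#> class_2 -5  3 -5
#> Tie policy: reject

predict(fit, rbind(c(6, 5, 2), c(4, 7, -1), c(1, 8, -3)), type = "scores")
#> # A tibble: 3 × 5
#>   .score_class_1 .score_class_2 .decision  .pred_index .pred_class
#>            <dbl>          <dbl> <chr>            <int> <chr>
#> 1             59            -59 classified           1 class_1
#> 2             28            -28 classified           1 class_1
#> 3              0              0 neutral             NA <NA>
```

The undistorted pattern scores z = (59, −59) and recovers class 1; the
distorted pattern (4, 7, −1) still lands on class 1 with z = (28, −28);
the mean vector itself is the neutral point and is rejected.
`apc_demo()` prints this walk-through and verifies every quantity.

A stochastic run — APC under stratified 50/50 holdout, 100 repetitions, on
a well-separated synthetic two-class problem with the 458/241 imbalance:

```r
d <- synth_gaussian(list(rep(0, 9), rep(10/3, 9)), 1, c(458, 241), seed = 42)
plan <- stratified_holdout(d$class, 0.5, repetitions = 100, base_seed = 42)
glance(evaluate_classifier(d, apc_classifier(), plan))
#> # A tibble: 1 × 7
#>   classifier protocol units failed_units mean_accuracy sd_accuracy mean_rejection_rate
#> 1 APC        holdout    100            0             1           0                   0
```

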