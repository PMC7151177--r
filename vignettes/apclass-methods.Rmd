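---
title: "The associative pattern classifier: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The associative pattern classifier: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apclass)
```

## The model

`apclass` implements a one-shot associative-memory classifier for
real-valued feature vectors.  It is a hybrid of two classical memories:
the *linear associator*, whose Hebbian learning accumulates outer products
of input/output pairs into a correlation matrix, and the *Lernmatrix*,
whose recovery takes the row with maximal activation.  The classical
linear associator only recalls reliably when inputs are (near-)orthogonal
and few relative to their dimension; the Lernmatrix only accepts binary
vectors.  The hybrid removes both restrictions by a single preprocessing
step — translating every pattern by the fundamental set's mean — and by
using one-hot class labels as the output patterns.

Given p training pairs $(\mathbf{x}_k, c_k)$ with
$\mathbf{x}_k \in \mathbb{R}^n$ and $c_k \in \{1,\dots,m\}$, encoded
one-hot as $\mathbf{y}_k \in \{0,1\}^m$:

$$\bar{\mathbf{x}} = \frac{1}{p}\sum_k \mathbf{x}_k,
  \qquad
  \mathbf{M} = \sum_k \mathbf{y}_k\,(\mathbf{x}_k - \bar{\mathbf{x}})^{\mathsf T}.$$

Row $j$ of $\mathbf{M}$ is simply the sum of the translated patterns of
class $j$.  A query $\mathbf{x}_\omega$ is scored as
$\mathbf{z} = \mathbf{M}(\mathbf{x}_\omega - \bar{\mathbf{x}})$, and the
decision is the index of the strictly unique maximum of $\mathbf{z}$.
Equivalently, $z_j$ is the summed inner product of the translated query
with the translated training patterns of class $j$ — the property the test
suite exploits as an independent oracle.

Three consequences shape the implementation:

- **Zero row-sum.**  Translated patterns sum to the zero vector, so the
  rows of $\mathbf{M}$ do too.  This is checked (with tolerance
  $10^{-9}\max(1, \max|M_{ij}|)$) at every fit and exposed in
  `glance()`.
- **Two-class antisymmetry.**  With $m = 2$, $z_2 = -z_1$: the scores for
  the worked example come out as $(59, -59)$ and $(28, -28)$.
- **The neutral zone.**  If the translated query is the zero vector —
  i.e. the query coincides with $\bar{\mathbf{x}}$ — then
  $\mathbf{z} = \mathbf{0}$ and no class can be recovered.  The
  classifier reports this as an explicit *neutral* decision rather than
  guessing.

For two balanced classes the decision rule is algebraically the
nearest-class-centroid rule (minimum Euclidean distance), because row $j$
is then $p_j(\bar{\mathbf{x}}_j - \bar{\mathbf{x}})$ with equal $p_j$.
The package's native minimum-distance classifier (`mdc_classifier()`)
doubles as a cross-check of this equivalence in the property tests.

## Decision semantics and tunable parameters

`apc()` and the scoring functions expose a small number of knobs:

- **`tie_policy`** (default `"reject"`): a tied non-zero maximum is
  reported as *ambiguous* and left unclassified.  The alternative
  `"lowest_index"` breaks the tie to the smallest tied class index.
  Rejection is the default because the neutral zone is defined as
  "cannot be classified", and treating near-degenerate evidence the same
  way is the conservative reading; the evaluation harness then counts
  every rejection as an error, so the reported accuracies are never
  flattered by the reject option.
- **Neutral tolerance.**  Exact zero is a measure-zero event in floating
  point, so $\mathbf{z}$ counts as all-zero when
  $\max_j |z_j| \le 10^{-9}(1 + \max|M_{ij}| \cdot \max|x_{t,i}|)$.
  The same band is used to detect ties at the maximum.  The scale factor
  makes the band unit-free: scores scale quadratically with the data
  (scaling patterns and query by $s$ multiplies $\mathbf{z}$ by $s^2$, a
  tested property), and an absolute constant would misfire at extreme
  magnitudes.
- **Class indices are 1-based** everywhere a user sees them, and class
  *names* (not indices) are the interface of the tidy functions.
- **No feature scaling** is applied anywhere: the learning rule is used on
  raw features (the cytology features it was designed around are already
  on a common 1–10 scale).  Scale *equivariance* of the scores means
  rescaling would not change decisions anyway, but per-feature
  standardization would, and is deliberately left to the user.
- **Degenerate inputs.**  A dataset whose patterns are all identical
  yields $\mathbf{M} = \mathbf{0}$ and every query neutral (tested).
  A class with no training pattern leaves its matrix row undefined, so
  fitting rejects it by name; single-class datasets are rejected for the
  same reason — with one class the translated patterns sum to zero and
  the model can never produce a non-neutral decision.

Models serialize to a versioned JSON document (`write_apc()`/`read_apc()`)
with numbers written at 17 significant digits, which round-trips IEEE
doubles bit-faithfully; the test suite asserts the round trip.

## Data input and missing values

The native dialect is the Wisconsin Breast Cancer (Original) file: 11
comma-separated fields — sample id, 9 integer features in 1–10, class code
2 (benign) or 4 (malignant) — with `?` for a missing cell.  The reader is
strict: wrong arity, non-numeric features, and unknown class codes are
parse errors that name the offending line, and nothing is dropped
silently.  Values outside 1–10 only warn, because the file's historical
revisions changed 0s to 1s and a permissive-but-loud reader is more useful
against older copies.  Benign is always class 1 and malignant class 2, for
determinism across runs.  A generic labeled-CSV reader handles other
tabular data, indexing classes in first-appearance order.

Missing values follow a declared `missing_policy()`:
`impute_global_mean` (default), `drop_record`, or `impute_constant`.
The default keeps the full 699-record framing of the native dataset while
`drop_record` reproduces the common 683-record convention.  During
evaluation, imputation statistics are computed **from the training portion
of each split only** — a canary test perturbs test-set values after
fitting and asserts the fitted model is unchanged.  `drop_record` must be
applied before building a split plan (dropping inside a unit would
silently change test denominators), and the harness enforces that.

## Evaluation protocol

`stratified_holdout(labels, fraction, repetitions, base_seed)` draws
independent stratified splits; per class the training count is
round-half-up(fraction × class size) floored at 1, so even a 1% training
fraction leaves every matrix row defined (on a 458/241 dataset this gives
5/2 training patterns at 1% and 229/121 at 50%).  Repetition $r$ uses seed
`base_seed + r`, making every plan reproducible and every repetition an
independent re-stratification rather than a nested subset.
`stratified_kfold(labels, k, repetitions, base_seed)` deals each shuffled
class round-robin into k folds (per-class fold sizes differ by at most
one).  The fraction grid `c(0.01, 0.1, 0.3, 0.5, 0.7)` with 100
repetitions, and 10-fold with 10 repetitions, reproduce the standard
benchmarking protocol for this classifier family; `learning_curve()` runs
the grid in one call and is the tool for locating where accuracy
stabilises — for the APC that point sits around a training set one tenth
the size of the smallest class, which the curve lets you inspect rather
than asserting a threshold.

Accuracy is correct/|test| with rejections counted as errors, for
comparability with baselines that always emit a class.  Baselines beyond
the native minimum-distance classifier (naive Bayes, k-NN, SVM, a small
backpropagation network, a CART tree standing in for C4.5) are thin
adapters over **e1071**, **class**, **nnet** and **rpart** — the original
descriptions of those comparison methods carry no reproducible
hyperparameters, so reimplementing them would be invention; the adapters
use the delegates' defaults and their results should be read as
indicative.  A missing delegate package degrades to "skipped" in the
benchmark listing.

## The synthetic generator

`synth_gaussian()` draws m-class Gaussian data with configurable means,
shared covariance (per-class covariance behind an explicit flag, because
the balanced-class equivalence with the centroid rule presumes no
per-class scaling), class sizes and seed.  `wbcd_like_fixture()` shapes
it like the native database: 699 records, 458 benign (mean 2.5) / 241
malignant (mean 7), per-feature standard deviation 1.8, rounded then
clamped to 1–10, and 16 missing cells all in the bare-nuclei column, one
per affected record.  Those class-conditional parameters were fixed once
as a realistic cytology-like configuration: integer features spanning the
scale with overlapping but well-separated class modes.

What the fixture emulates is the *shape* of the real data — schema,
integer range, class imbalance, missing-cell placement — so the file
dialect, the policies and the protocols can be exercised end-to-end
offline.  What it does not emulate: the real features' correlation
structure, skew, and the actual difficulty of the diagnostic problem.
Passing tests on synthetic data therefore validate the machinery and the
classifier's mathematical properties, not clinical performance; published
accuracies on the real database are only meaningful when rerun on the
genuine file (`scripts/wbcd_benchmark.R`), and small differences from any
published figure are expected because the original experiments' seeds are
unstated.

The stochastic test conditions are fixed in code: chance-level behaviour
is checked on coincident-mean balanced classes (9 features, σ = 1, 50+50
records, 20 seeds, accuracy within 0.5 ± 0.1); near-separable behaviour on
10σ-separated means (same sizes, mean accuracy ≥ 0.99); and a separation
sweep over {0, 1, 2, 4, 8}·σ averaged over 20 seeds must be monotone up to
one inversion of ≤ 0.01.  Property suites run at desk scale — 100 random
instances with n ≤ 10, p ≤ 50, m ≤ 4 for the oracle equivalence, 100
random balanced sets for the centroid equivalence — sizes at which the
whole suite runs in seconds while still exercising every code path.

## Known limitations

- The APC is a linear-prototype classifier; classes that are not
  separable by distance to a summed-translation prototype (e.g. nested or
  multi-modal classes) are beyond it, whatever the evaluation says on
  Gaussian data.
- Scores are uncalibrated; $\mathbf{z}$ orders classes but is not a
  probability, and no multi-label output exists.
- Heavily imbalanced multi-class problems skew the prototype rows by
  class count; the package reports per-class training counts but applies
  no reweighting.
- The reject option handles only exact/near ties and the neutral point;
  there is no confidence-band rejection.
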