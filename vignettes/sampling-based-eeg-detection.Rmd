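---
title: "Sampling-based detection of multicategory EEG signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling-based detection of multicategory EEG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsample)
```

## The problem and the model

Long multichannel EEG recordings are nonstationary: their amplitude
statistics drift over time, and a single summary computed over a whole
recording blurs distinct regimes together. `eegsample` implements a
detection pipeline that treats the time axis of each per-class recording
as a *finite population to be surveyed* rather than a signal to be
transformed:

1. **Segmentation.** Each recording of length $L$ is split into $k$
   contiguous, non-overlapping segments. The first $k-1$ segments have
   $\lfloor L/k \rfloor$ points; the remainder goes to the last segment
   (so $L = 4097$, $k = 4$ gives 1024, 1024, 1024, 1025). Appending the
   remainder to the last segment, rather than spreading it, is what makes
   the reference geometry come out exactly.

2. **Sample-size determination.** The required number of representative
   time points for a population of size $Popu$ is Cochran's formula with
   finite-population correction,
   $$SS = \frac{z^2\,p\,(1-p)}{e^2}, \qquad
     n = \left\lceil \frac{SS}{1 + (SS - 1)/Popu} \right\rceil ,$$
   with $z$ the standard-normal quantile of the confidence level, $p$ the
   assumed proportion and $e$ the margin of error. The defaults $z = 2.58$
   (99% confidence), $p = 0.5$ (the conservative choice that maximizes
   $SS$) and $e = 0.01$ give $n = 965$ of 1024 points, 966 of 1025, and
   3288 of 4097. Rounding is always *up*: the size is a requirement, not
   an estimate. Note that the correction never returns $n = Popu$ except
   at $Popu = 1$; for finite $SS$ the ratio $SS\,Popu/(Popu + SS - 1)$
   stays strictly below $Popu$.

3. **Selection.** Under **random sampling (RS)** each segment is its own
   population: $n_i$ comes from the formula with $Popu = N_i$, and $n_i$
   indices are drawn uniformly without replacement inside segment $i$.
   Under **optimum-allocation sampling (OS)** the whole recording is the
   population; its budget $m$ is divided across segments proportional to
   $$w_i = N_i \sqrt{\textstyle\sum_{j} s_{ij}^2},$$
   where $s_{ij}^2$ is the variance of channel $j$ within segment $i$ —
   longer and more variable segments are sampled more heavily.

4. **Features.** From each channel's pooled sampled values, eleven
   statistics: mean, median, mode, first and third quartile, interquartile
   range, standard deviation, skewness, kurtosis, minimum and maximum.

5. **Detection.** k-nearest neighbours, multinomial logistic regression
   with a ridge estimator, or a one-vs-one RBF SVM, evaluated by
   stratified 10-fold cross-validation, with the whole sampling procedure
   repeated (20 times by default) and the metric panel averaged.

## Numerical conventions

Several steps are only defined up to a convention; the package fixes each
one deterministically so runs are exactly repeatable.

* **Integer allocation.** The OS shares $w_i/\sum w \cdot m$ are rarely
  integers. They are rounded by largest-remainder (Hamilton)
  apportionment, which conserves $\sum n_i = m$ exactly; remainder ties
  break toward the earlier segment. An allocation exceeding its segment
  length is capped at $N_i$ and the surplus reallocated among the
  uncapped segments by the same rule.
* **Quantiles** interpolate linearly at rank $(n-1)q$ (the common
  "type 7" rule).
* **Variance and moments.** The standard deviation uses the $n-1$
  denominator. Skewness and kurtosis are the biased central-moment ratios
  $g_1 = m_3/m_2^{3/2}$ and $g_2 = m_4/m_2^2 - 3$; kurtosis is reported
  as *excess*, so a normal signal scores 0, which is the reading under
  which "matches the normal distribution" is a test against zero. A
  constant input has $g_1 = g_2 = 0$ by convention.
* **Mode.** The midpoint of the fullest bin of an equal-width histogram
  with $\lceil\sqrt{n}\rceil$ bins over $[\min, \max]$; ties go to the
  lowest bin; a degenerate range returns the common value.
* **Normalization.** Features have wildly different scales (an amplitude
  maximum versus a dimensionless skewness), so distance-based k-NN needs
  a stated convention: per-feature min-max scaling to $[0,1]$, fitted on
  the training fold only and applied to test rows with values clipped to
  the guard range $[-0.5, 1.5]$. It is applied before all three
  classifiers (configurable: `zscore`, `none`).
* **k-NN ties.** A vote tie goes to the single nearest neighbour's
  label; a distance tie goes to the lower training-row index.
* **MLR.** Coefficients form an $(m{+}1)\times(K{-}1)$ matrix with the
  last class as reference; the ridge penalty $\lambda \sum B^2$ excludes
  the intercept row, so at huge $\lambda$ the predicted probabilities
  collapse to the class priors rather than to nonsense. The objective is
  minimized by BFGS (a quasi-Newton method) with the analytic gradient,
  which the tests check against central finite differences. The default
  $\lambda = 10^{-8}$ is a numerical stabilizer, not a tuned
  regularizer. Convergence is declared at gradient max-norm
  $\le 10^{-3}$: with near-separable data and a vanishing ridge the
  likelihood surface flattens while predictions are long since stable,
  so a stricter norm would only burn iterations.
* **SVM.** One binary soft-margin RBF machine per class pair
  ($K(K-1)/2$ in all), combined by pairwise voting; argmax ties go to
  the class earliest in label order. The binary quadratic program is
  solved by libsvm via `e1071`; the decomposition and voting rule live
  here. Defaults $C = 1$ and $\gamma = 1/11$ (one over the feature
  count): the literature's "default C" expression for this pipeline is
  not interpretable as printed, so the package uses the plain libsvm
  default and leaves both configurable.
* **Evaluation.** Per-fold predictions are pooled into one confusion
  matrix per repetition before metrics are computed (fold-averaging is
  the other defensible reading; pooling is pinned by tests). Per-class
  "accuracy" is reported as that class's recall, and overall values are
  unweighted macro means — the conventions under which published
  per-class/overall tables of this kind are internally consistent. Kappa
  is computed from the pooled confusion matrix, MAE as the mean absolute
  difference between the score matrix and the one-hot truth (uniform
  scores over $K$ classes give exactly $2(K-1)/K^2$), and ROC area as
  the rank statistic with ties counted half.
* **Seeds.** Repetition $r$ uses base seed $+\,(r-1)$; within a
  repetition, class $c$ draws its indices with offset $131c$ so classes
  get independent draws, and the CV shuffle reuses the repetition seed.
  Identical configuration and corpus give bitwise-identical reports.

## The synthetic corpus generator

Real benchmark recordings cannot be bundled, so `generate_benchmark()`
produces corpora in the same layout (classes × channels × samples, one
ASCII file per channel on disk). Each channel is an AR(1) series
$x_t = \varphi x_{t-1} + e_t$ with $\varphi = 0.5$, driven by
standardized skew-normal innovations whose SD switches between segments
— the kind of amplitude nonstationarity that motivates segmentation,
and enough structure to make the OS weights nontrivial. Classes are
spaced by a `separation` parameter in innovation SD and skewness;
five-class corpora give the last ("seizure-like") class an extra
constant 2.5× amplitude factor, mirroring the few-fold larger ictal
amplitudes of real data. At `separation = 0` every class spec is
literally identical — the per-segment variance rotation and the
seizure boost fade with separation — so a classifier should sit at
chance, which the test suite checks (a useful leak detector: any
above-chance accuracy there means information is crossing where none
should).

What the generator does **not** emulate: spectral peaks, spike-wave
morphology, artifacts, inter-channel correlation. Passing tests
demonstrate that the pipeline recovers *amplitude-statistics* class
structure; they say nothing about performance on real EEG, which is why
published real-data accuracies are not asserted anywhere in the suite.

## Problem sizes used by the tests

The suite exercises the full reference geometry once (5 classes × 100
channels × 4097 samples) to pin the 500 × 11 feature-matrix shape and
the exact 50-row stratified folds. Everything else runs on scaled-down
corpora (typically 5 × 20 × 1024 or smaller, 1–2 repetitions), which
the generator's design keeps statistically equivalent for the
properties under test: end-to-end recovery uses `separation = 8`
("well-separated", ≥ 95% macro accuracy expected) and `separation = 0`
(chance band 20% ± 8 points at 100 pooled predictions).

## A worked run

```{r example}
corpus <- generate_benchmark(n_classes = 5, n_channels = 20,
                             n_samples = 1024, seed = 1, separation = 4)
cfg <- run_config(scheme = "RS", confidence_z = 1.96, margin_e = 0.05,
                  classifier = "knn", n_folds = 10, n_repetitions = 2,
                  seed = 1)
report <- run_experiment(corpus, cfg)
report
```

The realized per-segment sizes table has the same layout as the
published sample-size tables; with the default 99%/0.01 design and
4097-point recordings it reads 965, 965, 965, 966 per class under RS.

## Known limitations

* The OS scheme estimates per-segment variances from the full data
  before sampling — it is a two-pass design, inherently.
* `select_k()` runs plain CV inside the training fold; the
  inner/outer nesting of the original protocol is not specified, so the
  default configuration pins $k = 1$ (the value that protocol selects)
  and leaves the search opt-in via `knn_k = NA`.
* Amplitudes are treated as unitless reals; no EDF/BDF readers, artifact
  rejection, filtering or resampling.
* MAE and ROC area require a score matrix; SVM scores are vote shares,
  not calibrated probabilities, so its MAE is not comparable to MLR's.
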