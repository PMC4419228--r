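# eegsample

Sampling-based feature extraction and detection of multicategory EEG
signals, for researchers who need a reproducible, offline-testable
implementation of the survey-sampling approach to EEG classification:
instead of transforming a long nonstationary recording, treat its time
axis as a finite population, segment it, and *survey* it.

## The method

For each class of recordings (e.g. the five-class problem: healthy
eyes-open Z / eyes-closed O, interictal N / F, seizure S):

1. Split each `L`-point recording into `k` contiguous segments; the
   first `k − 1` have `⌊L/k⌋` points and the last takes the remainder
   (`L = 4097`, `k = 4` → 1024, 1024, 1024, 1025).
2. Determine the required number of representative time points for a
   population of size `Popu` from Cochran's formula with the
   finite-population correction, rounded up:

   ```
   SS = z² p (1 − p) / e²          n = ⌈ SS / (1 + (SS − 1)/Popu) ⌉
   ```

   At 99% confidence (`z = 2.58`), `p = 0.5`, `e = 0.01`: 965 of 1024
   points, 966 of 1025, 3288 of 4097.
3. Select the points: **RS** (random sampling) draws `n_i` uniformly
   without replacement within each segment treated as its own
   population; **OS** (optimum-allocation sampling) computes one budget
   `m` for the whole recording and splits it across segments
   proportional to `N_i · √(Σ_j s²_ij)` — longer and more variable
   segments get more.
4. From each channel's pooled sample, extract eleven statistics (mean,
   median, mode, Q1, Q3, IQR, SD, skewness, excess kurtosis, min, max).
5. Classify the `(class, channel)` feature rows with k-NN, multinomial
   logistic regression with a ridge estimator, or a one-vs-one RBF SVM,
   under repeated stratified 10-fold cross-validation; report the panel
   of TPR, FAR, precision, recall, F-measure, accuracy, kappa, MAE and
   ROC area, averaged over sampling repetitions.

A seeded synthetic corpus generator (AR(1) channels with skewed,
segment-wise heteroscedastic innovations, in the same
directory-of-ASCII-files layout as the public benchmark corpus) makes
the whole pipeline testable without any download.

## Worked example

```r
library(eegsample)

corpus <- generate_benchmark(n_classes = 5, n_channels = 20,
                             n_samples = 1024, seed = 1, separation = 4)
cfg <- run_config(scheme = "RS", confidence_z = 1.96, margin_e = 0.05,
                  classifier = "knn", n_folds = 10, n_repetitions = 2,
                  seed = 1)
run_experiment(corpus, cfg)
```

```
<experiment_report: RS + knn, 2 repetition(s), 10-fold CV>

Realized sample sizes (repetition 1):
 class Seg1 Seg2 Seg3 Seg4 Total
     Z  154  154  154  154   616
     ...
     S  154  154  154  154   616

Overall mean (SE) over repetitions:
  TPR         97.500 (0.500)
  FAR          0.625 (0.125)
  precision   97.571 (0.524)
  recall      97.500 (0.500)
  F_value     97.499 (0.500)
  accuracy    97.500 (0.500)
  kappa        0.969 (0.006)
  MAE          0.010 (0.002)
  AUC          0.984 (0.003)
```

Reading this: each 1024-point recording was segmented into four parts
and surveyed at the 95%/e = 0.05 design (154 points per segment, 616 of
1024 per channel); the five synthetic classes, spaced 4 baseline-SDs
apart, are recovered at 97.5% macro accuracy with kappa 0.97 and near-0
false-alarm rate. `run_experiment()` is bitwise-reproducible for a fixed
seed. `write_experiment_report()` dumps `report.json`, `report.csv` and
per-repetition confusion matrices.

A thin command-line front end (`inst/cli/eegsample.R`) exposes the same
pipeline as subcommands:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/eegsample.R", package="eegsample"))')" \
  generate --out corpus --classes 5 --channels 20 --samples 1024 --seed 1
...                 # sample / features / classify / run
```

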