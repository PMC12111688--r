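# emoKAN

Emotion recognition from **four frontal EEG channels** (FP1, FP2, AF3,
AF4). Laboratory emotion-EEG datasets are recorded with 32-62 electrodes,
but wearable devices carry a handful; this package implements a complete
sparse-channel pipeline for researchers who want to classify affective
state from exactly the frontal electrodes practical headsets provide, and
to study each stage in isolation.

The pipeline:

1. **Band features** — per 1-second window and band (theta 4-8, alpha
   8-13, beta 13-30, gamma 30-45 Hz): differential entropy
   `DE = ½ ln(2πeσ²)` of the zero-phase band-filtered signal, Welch band
   power `∫ PSD(f) df`, the theta log-power ratio
   `EVI = ln(P₁/P₂)` and the asymmetry index
   `ASI = (P₁−P₂)/(P₁+P₂)` over four channel pairs — 48 features per
   window.
2. **Individual-difference correction** — features are min-max scaled to
   [0,1] on the training split, then the mean of each trial's 3-second
   pre-stimulus baseline is subtracted: `F_corrected = F′ − F̄ ∈ [−1,1]`.
3. **Pseudo-RGB mapping** — the 48 features fill a 4×4×3 image (planes:
   DE, power, EVI/ASI; rows: bands; columns: channels/pairs).
4. **CNN-KAN-F2CA classifier** — three 3×3 convolutions (32/64/64,
   batch-norm, dropout 0.5/0.4/0.3), a frequency-channel attention block
   (global average pool → real part of the full-length DFT → 64→8→64
   sigmoid bottleneck → per-channel rescaling), a 256-unit dense layer and
   a Kolmogorov-Arnold head (SiLU linear path + learnable cubic B-spline
   path with per-edge scalers). Trained with Adam, cross-entropy + L2,
   10-fold cross-validation, support-weighted metrics. The three ablation
   variants (`cnn`, `cnn_fcn`, `cnn_kan`) are built by the same
   constructor; the `cnn`/`cnn_fcn` variants reproduce the published
   320,388 / 352,772 parameter totals exactly, and inserting the attention
   block adds exactly 1,096 parameters.

A synthetic 4-channel EEG generator (1/f background plus band-limited
oscillations with class-specific gains and asymmetries, DEAP-shaped
trials) makes the whole pipeline testable without the license-gated DEAP
and SEED downloads; adapters for both datasets' MATLAB releases are
included. The training engine is single-precision RcppArmadillo with
gradients verified against double-precision finite differences.

## Worked example

```r
library(emoKAN)

# simulate a small merged dataset: 4 emotion classes x 8 trials, 63 s at 128 Hz
trials <- simulateDataset(synthConfig(), nTrialsPerClass = 8, seed = 2024)
fs <- datasetFeatures(trials)
fs
#> FeatureSet: 48 features x 2016 windows (96 baseline, 1920 experimental), 32 trial(s)
#> assays: features

# 3-fold CV with the full model, 30 epochs (desk scale)
cv <- runCV(fs, modelConfig("cnn_kan_f2ca"),
            trainConfig(epochs = 30, folds = 3, seed = 2024))
cv$summary
#>      metric      mean          sd
#> 1  accuracy 0.9640625 0.011267348
#> 2 precision 0.9683870 0.009020318
#> 3    recall 0.9640625 0.011267348
#> 4        f1 0.9644320 0.011026973
```

Accuracy is the fraction of held-out 1-second windows whose quadrant class
(HVHA/HVLA/LVHA/LVLA) is recovered; precision/recall/F1 are support-
weighted across classes (for single-label data weighted recall equals
accuracy). Chance level is 25 % — `runCV(..., shuffleLabels = TRUE)` runs
the permutation null. At the full protocol scale (40 trials per class,
10 folds) mean accuracy is close to 99 % and the null sits at chance.

Single pieces are exported too:

```r
countParams(buildModel(modelConfig("cnn")))   # 320388
f2caParamCount(64, 8)                         # 1096
deFromVariance(1)                             # 1.418939
asi(3, 1)                                     # 0.5
```

A command-line wrapper lives at `inst/scripts/run_cv.R` (synthetic data or
DEAP/SEED `.mat` inputs).

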