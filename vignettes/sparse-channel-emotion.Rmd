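---
title: "Sparse-channel EEG emotion recognition: features, correction, and the CNN-KAN-F2CA classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-channel EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoKAN)
```

## The problem

Wearable EEG devices record from a handful of electrodes, not the 32- or
62-channel caps of laboratory datasets. This package implements an emotion
classification pipeline designed for exactly four frontal channels — FP1,
FP2, AF3 and AF4 — the electrodes most practical headsets cover and the
region where affective asymmetries are strongest. The pipeline has four
stages: band-limited feature extraction from 1-second windows, correction
of individual differences against a pre-stimulus baseline, arrangement of
the features into a small pseudo-RGB image, and classification with a
compact convolutional network whose head is a Kolmogorov-Arnold (B-spline)
layer and whose channel attention uses a Fourier descriptor.

## Features (48 per window)

Each 1-second window yields, over the four bands theta (4-8 Hz), alpha
(8-13), beta (13-30) and gamma (30-45 Hz):

* **Differential entropy (DE), 16 values.** For a band-filtered segment
  assumed Gaussian, $DE = \tfrac12\ln(2\pi e\,\sigma^2)$ nats, with
  $\sigma^2$ the variance of the zero-phase Butterworth-filtered channel.
  The natural logarithm is used throughout; the $2\pi e$ form presumes it.
* **Band power ("PSD"), 16 values.** The Welch spectral density integrated
  over the band, $\int_{f_1}^{f_2} PSD(f)\,df$, in $\mu V^2$. For 1-second
  windows the Welch default (segments of min(n, 256) samples, Hann window,
  50 % overlap) reduces to a single Hann periodogram. Band intervals are
  half-open $[f_1, f_2)$ so the four bands partition 4-45 Hz.
* **Spatial asymmetries, 16 values.** Four theta-band EVI values
  $\ln(P_{ch1}/P_{ch2})$ over the pairs FP1-FP2, AF3-AF4, FP1-AF4 and
  AF3-FP2, and twelve ASI values $(P_1-P_2)/(P_1+P_2)$ for alpha, beta and
  gamma over the same pairs. ASI is bounded in $[-1,1]$; both are
  antisymmetric under swapping the pair.

Canonical ordering inside each 16-block is band-major, channel- (or pair-)
minor; `featureNames()` and `featureLayout()` document the exact layout and
its bijection to tensor coordinates.

Numerical choices worth stating: band filtering uses a Butterworth design
of order 4 applied forward and backward (`signal::filtfilt`), with the
channel mean removed first and odd-reflection padding — without these,
filter edge transients leak a DC-dependent bias into 1-second-window
variances. Windows with zero variance or zero band power raise a
degenerate-signal error rather than returning $-\infty$; the pipeline
treats such windows as malformed input. Whether "PSD feature" means
density or band-integrated power is a genuine ambiguity; we use integrated
power (the band edges are explicit, and the integral is what Parseval
constrains).

## Individual-difference correction

Trials open with a 3-second pre-stimulus baseline (the DEAP/SEED layout).
The baseline is cut into three 1-second windows and featurized like any
other window. Correction then proceeds in the stated order *normalize,
then subtract*:

1. min-max scale every feature to $[0,1]$ using ranges fitted on a
   training split only (`fitMinMax()` / `applyMinMax()`); out-of-range
   values in validation or test data are clipped, and degenerate constant
   features map to 0 with a warning;
2. per trial, subtract the mean of the scaled baseline windows from the
   scaled experimental windows ($F_{corrected} = F' - \bar F$), leaving
   corrected features in $[-1,1]$.

Baseline windows exist only to supply $\bar F$; they are never fed to the
classifier. The scope of the min-max fit is not dictated by the protocol
we follow, so the default is the leakage-free choice — refit inside each
cross-validation fold on its training windows — with a `"global"` mode
available for parity with a whole-dataset fit.

## Pseudo-RGB mapping

The 48 corrected features of a window fill a $4\times4\times3$ tensor:
plane 1 DE, plane 2 band power, plane 3 the spatial block; rows are bands,
columns are channels (or pairs; the theta row of the spatial plane carries
the four EVI values). Keeping each band's cross-channel pattern in one row
means a $3\times3$ convolution sees adjacent bands and adjacent channels
together. Batches are `(N, 4, 4, 3)` arrays (`featureSetToBatch()`).

## The classifier family

`buildModel()` assembles four ablation variants on a shared backbone of
three $3\times3$ same-padding convolutions with 32, 64 and 64 filters, each
followed by batch normalization, ReLU and dropout (0.5, 0.4, 0.3). "Kernel
sizes of 32, 64 and 64" is read as filter counts; $3\times3$/same with no
pooling is the only standard choice under which the flattened map is 1024
wide and the published totals decompose exactly. The flattened map feeds a
256-unit dense layer (dropout 0.5), then the head:

| variant | head | total parameters (4 classes) |
|---|---|---|
| `cnn` | softmax dense | 320,388 |
| `cnn_fcn` | dense 128 + softmax dense | 352,772 |
| `cnn_kan` | KAN(256→128) + softmax dense | 647,556 |
| `cnn_kan_f2ca` | F2CA after conv 3, then as `cnn_kan` | 648,652 |

Parameter counts include the batch-norm moving statistics — the convention
under which the `cnn` total decomposes exactly as
$896 + 18{,}496 + 36{,}928 + 640 + 262{,}400 + 1{,}028$. The KAN variants'
totals depend on spline hyperparameters that cannot be recovered from the
published total alone; with our defaults (grid 5, order 3) the KAN layer
holds $256\cdot128\cdot(2+5+3) = 327{,}680$ parameters. What *is*
determined exactly is the attention block's size: two biased dense layers
$64 \to 8 \to 64$ contribute $(64\cdot8+8)+(8\cdot64+64) = 1{,}096$
parameters, matching the printed difference between the two largest
variants. That parity forces two design readings: the Fourier descriptor
keeps full length C (not a half spectrum), and both excitation layers
carry biases.

**F2CA.** On the $4\times4\times64$ map after the third convolution:
global average pooling gives a 64-vector $v_1$; the descriptor is the real
part of its full-length DFT (unnormalized — the $1/C$ convention is not
fixed by the math, so it is configurable); a bottleneck
ReLU–sigmoid MLP with ratio 8 produces per-channel gates in $(0,1)$, which
rescale the map. Unlike plain squeeze-and-excitation, the DFT mixes all
channel means into every descriptor entry.

**KAN layer.** Each output sums a SiLU base path,
$\mathrm{SiLU}(X)W_{base}$, and a spline path in which every (input,
output) edge carries a learnable univariate cubic B-spline
($\sum_k B_k(x_i) W_{spline}[i,o,k]$, Cox–de Boor basis) weighted by a
per-edge adaptive scaler. The grid is uniform over $[-1,1]$ with 5
intervals — corrected features are bounded, and the dense activations that
reach the layer stay mostly within the span. Inputs outside the span are
clamped *for basis evaluation only*, so the base path (and its gradient)
still flows; this avoids both zero-basis dead zones and dead units.

**Sample-group fusion.** The protocol groups 12 windows sharing a trial
label; `fuseGroup()` fuses their embeddings by mean (or concatenation).
In window-level cross-validation a trial's windows may span folds, so
fusing across them would leak test information into training; the CV
driver therefore classifies windows individually by default and exposes
fusion as an explicit operation.

## Training and evaluation

The engine minimizes categorical cross-entropy plus an L2 penalty
(coefficient 0.001 on weight matrices) with Adam (learning rate 0.0005,
batch 512), fixed epochs, no early stopping. It is written in single
precision on top of BLAS matrix products, with convolutions as im2col
matrix multiplies; gradients for every layer are verified in the test
suite against double-precision finite differences of an independent R
replica. Dropout and shuffling derive from one seeded generator, so runs
are reproducible bit-for-bit given a seed (2024 by default).

`runCV()` shuffles windows (seeded), splits them into 10 folds, refits
normalization per fold, trains per fold and reports accuracy and
support-weighted precision/recall/F1 (`computeMetrics()`, verified against
a brute-force one-vs-rest oracle; for single-label problems weighted
recall equals accuracy identically). Window-level splitting follows the
source protocol but lets correlated windows of one trial appear on both
sides of a fold — a known optimistic bias of that protocol which we
document rather than hide; the remedy (trial-grouped splits) can be had
by assigning folds per trial before featurization.

## The synthetic generator

Real DEAP/SEED recordings are license-gated, so the package ships a
generator (`synthConfig()`, `simulateTrial()`) that emulates the trial
structure the pipeline expects: 63 s at 128 Hz, a 3-s class-neutral
baseline, then an experimental segment. Each channel sums four
band-limited oscillations (band-passed Gaussian noise, RMS amplitudes
theta 4, alpha 5, beta 3.5, gamma 2.5 µV) and a $1/f$ background
(RMS 12 µV, support 4-45 Hz). Classes act multiplicatively on oscillation
amplitudes: each of the four quadrant classes raises one band globally
(gain 2) and lateralizes another (gain 3 on one side of the homologous
pairs), giving every class a distinct power-plus-asymmetry signature.
Lognormal per-trial jitter (sd 0.1) and a per-subject global scale
(sd 0.2) emulate trial-to-trial and between-subject variability; the
subject scale is exactly the nuisance the baseline correction removes.
The background RMS was fixed by a small pilot so that a gain-3 class
measures a mean windowed ASI near 0.55 — power ratio 9 attenuated by the
noise floor — rather than the noiseless 0.8.

What the generator does *not* emulate: eye-blink and muscle artifacts,
non-stationary drift, volume-conduction correlation between channels, and
realistic class overlap. Synthetic classes are deliberately separable, so
a high cross-validated accuracy here demonstrates that the pipeline is
correct and can recover known structure — not that comparable accuracy
would be reached on real recordings. The label-shuffled permutation null
(chance-level accuracy on the same features) guards against the reverse
failure, i.e. the pipeline manufacturing accuracy from leakage. The null
permutes labels at the *window* level — the unit the classifier
exchanges. Permuting whole-trial labels instead leaves each trial's
windows label-consistent, and under window-level folds the network then
scores well above chance by memorizing trial identity; that observation
quantifies the within-trial-correlation bias of window-level splitting
rather than invalidating the pipeline, and disappears under trial-grouped
folds.

Adapters for the datasets' MATLAB releases are included
(`readDeapSubject()`, `readSeedSession()`), built on a minimal MAT5
numeric-array reader/writer validated round-trip and against an
independent implementation; channels are always selected by montage name,
never by hard-coded index, DEAP ratings binarize at "rating > 5", and SEED
sessions get the 4-45 Hz band-pass on load.

## Problem sizes used in the shipped checks

The end-to-end check simulates 4 classes × 40 trials (9,600 experimental
windows), runs `cnn_kan_f2ca` for 30 epochs under 10-fold CV, and repeats
the run with permuted labels; correction-stage checks use 48 neutral 13-s
trials, and the generator realism check 40 neutral 63-s trials. These
sizes keep a full run on one CPU core in the tens of minutes while leaving
each measured quantity comfortably inside its tolerance.

## Known limitations

* The published protocol under-determines several details we had to fix:
  min-max scope, Welch segmenting, band edges, filter order, the KAN grid,
  and the DFT normalization. All are configurable; defaults are stated
  above and in the help pages.
* Published DEAP/SEED accuracies are not reproducible without the
  license-gated data; the adapters are tested on synthetic fixtures only.
* The engine implements exactly this architecture family; it is not a
  general-purpose autodiff framework.
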