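---
title: "Estimating left ventricular mass from the 12-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating left ventricular mass from the 12-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecglvm)
```

## The problem

Left ventricular hypertrophy (LVH) — a pathological increase in left
ventricular mass (LVM) — drives diastolic dysfunction, arrhythmia and
cardiac death, yet the ECG criteria used to screen for it (Sokolow–Lyon,
Cornell) trade on a handful of QRS voltages and are poorly sensitive.
Tomographic imaging measures LVM accurately (myocardial wall volume ×
1.05 g/mL) but is expensive and carries radiation/contrast exposure.
`ecglvm` implements a regression pipeline that estimates CT-scale LVM in
grams directly from a standard 10-second, 500 Hz 12-lead ECG together
with demographics (age, sex, height, weight) and the automatic ECG
parameters every interpretation system emits (QRS duration, P/R/T axes).

## The model

One synchronized single heartbeat — the middle beat of the recording,
cut with the same sample window across all 12 leads — is the waveform
input. The leads are split into groups (by default the electrical-plane
grouping: limb leads I, II, III, aVR, aVL, aVF and precordial leads
V1–V6; a coronary-territory grouping LAD/LCx/RCA/LM is also available),
and each group is encoded by its own temporal convolutional network
(TCN): residual blocks of two dilated "same" convolutions with ReLU and
dropout, dilation growing geometrically with depth. The per-group
embeddings (global average pooling followed by a dense layer) are
concatenated and projected; demographics and ECG parameters pass through
their own small MLP branches after z-scoring with training-fold
statistics; the fused vector feeds an MLP regressor with a single linear
output in grams. Training minimizes the mean absolute error (MAE), and
the checkpoint with minimal validation MAE is kept.

The receptive field of a TCN with kernel $k$, dilation base $b$ and $n$
blocks (two convolutions per block) is
$R = 1 + \sum_{i=0}^{n-1} 2(k-1)b^i$; construction fails unless
$R \ge W$, the beat-window length, so every sample can influence the
embedding. The shipped default (5 blocks, 32 channels, kernel 7, base 2,
dropout 0.1) gives $R = 373 \ge 350$, covering the default −250 ms to
+450 ms window at 500 Hz. These hyperparameters are package defaults
chosen to satisfy that inequality with a compact model; they are all
configurable via `tcn_config()` and `model_spec()`.

Cross-validation uses the LVM-sorted systematic split: samples are
sorted by LVM (ties stable by index) and sorted position $j$ goes to
fold $j \bmod 5$, so folds have nearly identical LVM distributions (for
$n=1459$: test folds of 292/292/292/292/291, and per fold 1051–1052
training and 116 validation samples, the validation set being every 10th
sample of the sorted training portion). Sex-specific models filter all
three partitions to the target sex before training, motivated by sex
differences in LV remodelling and ECG voltage. LVH classification
derives from predicted LVM indexed to body surface area (Mosteller by
default, Du Bois optional) with strict thresholds of 72 g/m² (men) and
55 g/m² (women); the c-statistic uses the continuous predicted indexed
LVM as score (AUROC on hard labels would be degenerate).

## Gradient saliency and segment importance

For a trained model, the absolute gradient of the prediction with
respect to each input sample, $|\partial\hat y/\partial x_{l,t}|$, is a
saliency map (scalar-branch gradients are excluded; only the waveform is
tabulated). The beat is partitioned by its fiducial landmarks into PR
$[p_{on}, qrs_{on})$, QRS $[qrs_{on}, qrs_{off})$, ST-T
$[qrs_{off}, t_{off})$ and TP (the remainder, both flanks). Saliency is
summed over the eight (segment × limb/precordial) cells, each map is
normalized to 100 %, and percentages are averaged across maps — by
default five samples per low/middle/high LVM stratum (tertiles of the
ground truth; explicit bounds can be supplied). Normalize-then-average
was chosen (rather than average-then-normalize) so each patient
contributes equally. The backward pass is verified against central
finite differences in the test suite; a relative error below $10^{-3}$
on random coordinates is enforced.

## The synthetic cohort simulator

The real datasets this class of model is trained on are clinical and not
redistributable, so the package ships a seeded simulator that every
downstream stage is tested against. A heartbeat is a sum of five
Gaussians (P, Q, R, S, T), projected on the 12 leads by a fixed
physiologic amplitude matrix (aVR predominantly negative, V1 rS, V5–V6
tall R); fiducial landmarks are defined exactly as wave-center ± 3σ, so
ground truth is available to the sample. Covariates follow
sex ~ Bernoulli(0.5), sex-conditional Normal height (172 ± 7 /
159 ± 7 cm), weight 0.45·height − 8 + N(0, 9) kg, and

LVM = −155 + 1.2·height + 0.8·weight + 25·male + N(0, 15) g.

The fractional LVM excess over a 110 g reference then modulates the
waveform: R amplitude × (1 + 0.4·excess), QRS Gaussian widths ×
(1 + 0.2·excess), and an ST-level shift of −0.05·excess mV. These three
couplings, the covariate coefficients and the reference were fixed once
so that an n = 1000 cohort exhibits the qualitative structure expected
of a real CCTA cohort: corr(LVM, height) ≈ 0.77, corr(LVM, weight)
≈ 0.53, corr(LVM, QRS duration) ≈ 0.45, corr(LVM, R axis) ≈ −0.37, a
clear male–female LVM gap, and an LVH prevalence near 45 % under the
72/55 g/m² thresholds.

Crucially, the simulator also draws per-patient morphological
variability that is *independent* of LVM: a global voltage factor
(log-SD 0.12, body habitus/electrode placement), an independent
amplitude factor per wave (log-SD 0.12, so amplitude ratios such as R/T
are noisy), a QRS-width factor (log-SD 0.08) and an additive ST-level
offset (SD 0.03 mV). Without these, the waveform would be a noiseless
bijection of LVM and a waveform-only model would trivially dominate —
the opposite of what real cohorts show, where demographics add large
value over raw ECG. With them, an information calculation puts the best
achievable waveform-only error near 21 g against ~12 g when
demographics are available, so the simulator can express the documented
benefit of multimodal fusion. Heart rate is uniform in 55–95 bpm
(keeping ≥ 7 beats per 10 s record); records add Gaussian noise
(0.01 mV) and sinusoidal baseline wander (0.05 mV at 0.25 Hz). One
global seed drives per-row child seeds, so cohorts are extensible
without perturbing earlier rows and any record is regenerable
bit-identically from (seed, row).

What the simulator does **not** emulate: arrhythmias, bundle branch
block and paced rhythms (these are exclusion categories in the intended
cohort, not modelling targets), beat-to-beat variability, electrode
noise bursts, and any realistic torso volume-conduction physics. Tests
passing on this cohort therefore demonstrate that the pipeline recovers
a known, plausibly-structured signal — not that the architecture
reaches any particular accuracy on clinical data.

## Numerical and design choices

* **Filtering.** 3rd-order Butterworth 0.5–40 Hz, applied forward and
  backward (`signal::filtfilt`, zero phase). The band preserves ST-T
  morphology while removing baseline wander and mains-range noise. The
  zero-phase filter leaves small inter-wave baseline offsets (the
  high-pass removes each beat's local mean), which is why landmark
  delineation works on slopes, not amplitudes.
* **R-peak detection.** Derivative–squaring–moving-integration (150 ms
  window) on lead II (V5 fallback if II is flat), adaptive threshold at
  a quarter of the 99th percentile of the integrated energy, peak
  refinement to the absolute-amplitude maximum, 200 ms refractory. On
  noiseless synthetic records detection is within 2 ms of ground truth.
* **"Middle" beat.** Defined as the ⌊n/2⌋-th (0-based) of the eligible
  peaks, i.e. those whose full window fits inside the record.
* **Landmark delineation.** Thresholds on the smoothed derivative
  relative to the local maximum slope (QRS 4 %, T offset 5 %, P onset
  10 %, with 2–3-sample confirmation runs). On noiseless beats all four
  landmarks land within 20 ms of the generator's ± 3σ truth. On
  failure, or on noisy beats where slope thresholds cannot settle, the
  segment is flagged and fixed offsets relative to R (−200, −50, +50,
  +400 ms) are substituted; simulator ground truth, when supplied,
  always overrides detection.
* **Sample conventions.** 0-based sample indexing, half-open windows
  `[start, end)` everywhere; waveforms are stored time-major (L × 12)
  with canonical lead names as column names.
* **Initialization and optimization.** Fan-in-scaled uniform weights,
  Adam (lr 5·10⁻³ in the shipped training configurations), batch 64,
  early stopping on validation MAE. The output bias starts at the
  training-mean LVM so the network learns residual structure rather
  than the gross scale. Every stochastic step (weights, shuffling,
  dropout, validation draws) is driven by one integer seed; identical
  configurations reproduce identical histories bit for bit.
* **Imputation.** Missing scalars take the median of the *training*
  rows only; the statistics are stored and reused for validation, test
  and any new data, so held-out values can never leak into training.
* **Echo recalibration.** Cohorts whose ground truth is
  echocardiography-derived overestimate CT-scale LVM; a linear
  recalibration hook (`recalibrate_echo_lvm`) is provided, with the
  slope/intercept supplied by configuration since published calibrations
  vary.
* **Problem sizes.** The test-suite and acceptance runs train on an
  n = 1000 cohort with the single beat decimated 4× to 125 Hz — lossless
  for a 40 Hz-band-limited signal — using a 4-block, 16-channel TCN
  (receptive field 181 ≥ 88), 30 epochs. These sizes are the package's
  own choice of a compact, reproducible experiment; the full-resolution
  defaults remain 500 Hz with the 5-block, 32-channel encoder.

## Known limitations

The TCN and its training loop are implemented in base R over BLAS; it is
adequate for cohort sizes in the low thousands at decimated resolution,
but it is not a GPU deep-learning stack, and very large cohorts or
full-resolution training will be slow. Automatic landmark delineation is
designed for clean, averaged or synthetic beats; noisy clinical beats
routinely fall back to the fixed-offset landmarks (the saliency
aggregation is designed to tolerate this). The simulator's effect sizes
are stand-ins chosen for qualitative realism, not estimates of any
clinical dataset, and accuracy numbers obtained on it do not transfer to
real ECGs.
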