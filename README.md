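# ecglvm

Left ventricular mass (LVM) estimation from the 12-lead ECG with
lead-group temporal convolutional encoders.

## What this is for

Left ventricular hypertrophy — increased LVM, typically from chronic
pressure overload — predicts arrhythmia, diastolic dysfunction and
cardiac death, but classical voltage criteria on the ECG detect it
poorly, and the imaging that measures LVM accurately (CT, MR) is costly.
`ecglvm` is an R implementation of a multimodal regression pipeline for
researchers working on ECG-based cardiac structure inference: it
estimates CT-scale LVM (grams) from a synchronized single heartbeat of a
10-s, 500 Hz 12-lead ECG, fused with demographics and automatic ECG
parameters, and classifies LVH from the predicted indexed mass.

The core model encodes each lead group (limb vs precordial by default,
or coronary territories LAD/LCx/RCA/LM) with its own temporal
convolutional network — residual blocks of dilated convolutions whose
receptive field R = 1 + Σᵢ 2(k−1)bⁱ must cover the beat window —
concatenates the group embeddings with MLP-encoded scalar branches, and
regresses LVM under an MAE loss. Evaluation uses the LVM-sorted
systematic 5-fold split (sorted sample j → fold j mod 5), MAE/MAPE,
LVH metrics at the strict 72/55 g/m² indexed-LVM thresholds
(Mosteller BSA), a rank-based c-statistic, and gradient-saliency
importance of the PR/QRS/ST-T/TP beat segments. The network, its
backward pass and the Adam optimizer are implemented in base R over
BLAS — no deep-learning framework is required.

Because the clinical datasets such models are built on are not
redistributable, the package includes a seeded synthetic cohort
simulator (sum-of-Gaussians beats, 12-lead physiologic projection,
waveform morphology causally modulated by a known LVM, plus
LVM-independent per-patient morphological variability) against which
every stage is tested.

## Worked example

```r
library(ecglvm)

co  <- synthesize_cohort(300, seed = 11)          # 300 patients, 10 s ECGs
fit <- fit_lvm_net(co, input_set = "ecg_demo_params",
                   grouping = "electrical", decimate = 4L,
                   tcn = tcn_config(n_blocks = 4, channels = 16,
                                    embedding_dim = 32),
                   control = train_control(epochs = 20, lr = 5e-3, seed = 1))
print(fit)
#> ECG LVM network fit
#>   call: fit_lvm_net(cohort = co, input_set = "ecg_demo_params", ...
#>   input set ecg_demo_params, grouping electrical, sex scope all, 1 fold(s)
#>   test MAE 12.0 g, MAPE 12.3 %
```

The fit is an ordinary modelling object: `summary(fit)` adds per-fold
LVH classification metrics (accuracy, sensitivity, specificity, PPV,
F1, c-statistic), `predict(fit, newdata)` returns grams for new
records, `residuals(fit)`/`fitted(fit)` expose the out-of-sample
test-fold predictions, and `plot(fit)` shows predicted-vs-true LVM and
the training history. Here the model recovers the simulated cohort's
LVM to about 12 g / 12 % on held-out patients — against roughly 28 %
MAPE for predicting the training mean — with most of the gain coming
from the demographic branch, as expected when waveform morphology
carries LVM only noisily.

Segment-wise saliency shows which parts of the beat a waveform-only
model attends to:

```r
fit_ecg <- fit_lvm_net(co, input_set = "ecg_only", decimate = 4L,
                       tcn = tcn_config(n_blocks = 4, channels = 16,
                                        embedding_dim = 32),
                       control = train_control(epochs = 20, lr = 5e-3,
                                               seed = 1))
sal <- segment_saliency(fit_ecg, m = 5, seed = 1)  # 5 per LVM tertile
print(sal$high)
#> ECG-segment importance (%), averaged over 5 sample(s):
#>       limb precordial
#> PR     0.2        3.5
#> QRS    0.5       47.8
#> STT    0.7       47.1
#> TP     0.0        0.2
#> Total  1.3       98.7
```

Each table normalizes to 100 % across the eight (segment × lead-group)
cells. QRS and ST-T dominate and the precordial leads carry nearly all
of the attribution — consistent with how the simulator couples LVM to
the waveform (R amplitude, QRS width, ST level) and with the large
precordial voltages.

A thin command-line front-end over the same functions is included at
`inst/cli/ecglvm.R` (`synth` and `fit` subcommands).

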