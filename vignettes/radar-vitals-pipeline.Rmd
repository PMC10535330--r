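---
title: "Estimating heart and respiratory rate from UWB radar: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heart and respiratory rate from UWB radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarvitals)
```

## The problem

An ultra-wideband (UWB) pulse radar pointed at a sleeping child resolves
reflections into discrete range bins; each bin yields a slow (20 Hz)
baseband amplitude stream modulated by chest-wall motion. Respiration
moves the chest by millimetres, the heartbeat by tenths of a millimetre,
so both vital signs are encoded in the 0.2–4 Hz band of the amplitude
signal. `radarvitals` implements the full estimation pipeline: movement
screening of 10 s epochs, band-limited spectrogram images, a dual-branch
convolutional regressor that predicts heart rate (HR) and respiratory
rate (RR) simultaneously from each image, and Bland–Altman / correlation
evaluation under pooled 10-fold cross-validation. Because bedside
recordings of children are confidential by nature, the package also ships
a physically motivated simulator so every stage is testable and every
result in this vignette is reproducible from seeds.

## The synthetic radar model

Chest displacement is modelled as

$$d(t) = A_r\,\bigl(1 + m \sin(2\pi t/T_{pb})\bigr)\,\sin(2\pi f_r t)
       + A_c \sin(2\pi f_c t),$$

with $f_r = \mathrm{RR}/60$ and $f_c = \mathrm{HR}/60$. The modulation
index $m$ emulates *periodic breathing* — infant sleep respiration whose
tidal amplitude itself oscillates — and places sidebands at
$f_r \pm 1/T_{pb}$, which the spectrogram stage must tolerate.

Bin $b$, centered at range $r_b = \text{offset} + (b + \tfrac12)\,\Delta r$
(0-based $b$, bin length $\Delta r = 0.0388$ m, offset 0.3 m), receives

$$a_b(t) = \bigl|E(r_b)\,(1 + \kappa\, d(t)) + \varepsilon_b(t)\bigr|,$$

where $E$ is a Gaussian envelope centered at the subject's range with
width `range_spread`, $\kappa$ a linear displacement-to-amplitude gain,
and $\varepsilon$ i.i.d. Gaussian noise with standard deviation
`noise_sd` scaled by the device sensitivity as $(10 - \text{sens})/5$, so
the two sensitivity settings used in practice (5 and 9) differ
measurably. The modulus models envelope detection and keeps amplitudes
nonnegative. The linear small-motion map is deliberate: it makes the
spectral content of the amplitude equal that of the displacement, which
is all the downstream stages consume. Clutter (a nurse or parent leaning
into the zone) is injected as multiplicative `movement_event`s.

Default study conditions: 52 bins, 20 Hz, detection zone 0.4–1.0 m,
carrier 7.46 GHz (metadata only), one paediatric subject at 0.7 m with
HR 110 beats/min, RR 30 breaths/min, 5 mm respiratory and 0.5 mm cardiac
excursion, mild periodic breathing ($m = 0.3$, $T_{pb} = 15$ s), and
`noise_sd = 0.01` with $\kappa = 50\,\mathrm{m^{-1}}$ — chosen so that
clean quiet-sleep epochs score ≈100–180 movement units, comfortably
below the 300 exclusion threshold, while a single clutter event drives
affected epochs far above it. Reference vitals are emitted at 3 Hz, the
rate of a bedside patient monitor, constant unless a linear drift is
configured.

What the simulator does *not* emulate: real clutter statistics (it uses
box-car multiplicative events), multipath and occlusion, antenna
patterns, electromagnetic pulse shapes, multi-subject scenes, or the
heavy-tailed artefact structure of a paediatric intensive-care unit.
Passing tests on synthetic data therefore demonstrate the pipeline's
correctness and learnability under controlled physics, not clinical
performance.

## Movement score and exclusion

The movement score of a 10 s epoch is the summed absolute successive
difference of the amplitude matrix,
$S = \sum_b \sum_t |a_b(t+1) - a_b(t)|$, over **all** bins. Absolute
values are used because a signed sum would telescope to (last − first)
and could be negative, contradicting the score's role as a nonnegative
motion magnitude. Epochs tile the recording without overlap; a trailing
remainder is dropped with a warning.

Exclusion operates on tumbling 5-minute windows (30 epochs): a window is
discarded in full iff *strictly more than* 10 of its epochs score
*strictly more than* 300. Kept windows contribute all 30 epochs,
including the high-movement ones. A trailing partial window is judged by
the same strict count — the conservative reading, since a count rule on
fewer epochs can only be easier to satisfy. Both boundaries are strict
(`> 300`, `> 10`): a window with exactly ten epochs at 301, or thirty
epochs at exactly 300, is kept. Per-epoch labels are the arithmetic mean
of the thirty 3 Hz reference samples inside the epoch.

## Spectrogram images

Each kept epoch (200 samples) of each of 3 selected bins becomes a
short-time Fourier magnitude block:

* **Window**: 25-sample Hamming. The nominal 90% overlap implies a
  non-integer hop of 2.5 samples; hop 3 (88% overlap) is the unique
  integer hop that yields $\lfloor(200-25)/3\rfloor + 1 = 59$ frames per
  bin and hence the published 177 = 3 × 59 time columns. The hop is
  configurable.
* **Transform length**: 756. At 20 Hz this makes exactly 144 one-sided
  DFT bins (indices 8…151, spacing 20/756 ≈ 0.0265 Hz) fall inside the
  0.2–4.0 Hz analysis band, matching the published 144 frequency rows.
* **Demeaning and analytic signal** (defaults, configurable): the
  baseband amplitude carries a large DC baseline, and a 1.25 s window has
  a mainlobe of ±1.6 Hz. Without preprocessing, the DC leak and the
  negative-frequency mirror of a ~0.33 Hz respiratory tone dominate the
  band edge and drag the apparent peak ≈0.12 Hz low — several DFT bins.
  Removing the epoch mean and taking the analytic signal (FFT Hilbert
  transform) eliminates both; the respiratory and cardiac peaks then land
  within one DFT bin of truth on noise-free simulations. This is the
  package's numerical choice; the magnitude is kept linear (no dB).
* **Bin selection** reconciles "most variable" with "least range
  difference": the subject's bin is identified as the amplitude-variance
  argmax over kept epochs (ties to the smaller index), and its two
  nearest neighbours in range complete the triplet, clamped inward at
  array edges.
* **Image scaling**: each 144 × 177 image is min–max scaled to [0, 255]
  *per image* (an all-constant image maps to 0), removing absolute-gain
  dependence; it is then bilinearly resized to 224 × 224 and replicated
  across 3 channels for the convolutional backbone, followed by the
  backbone's input preprocessing (symmetric [−1, 1] scaling for the
  `tiny-test` backbone; ImageNet channel-mean subtraction for VGG-16).

## The dual-branch regressor

A frozen pretrained convolutional backbone is shared by two structurally
identical branches that fork after the last feature map — one per vital.
Each branch adds a 3 × 3 convolution with 16 filters (ReLU; the
activation of this added layer is not prescribed anywhere, so the
package matches the ReLU dense stack), 3 × 3 max-pooling, and dense
layers of 8 (ReLU), 4 (ReLU) and 1 (linear) unit. Training uses Adam
with learning rate 0.005 and the classic per-update inverse-time decay
$\eta_t = \eta/(1 + 0.001\,t)$ — the meaning "decay" had in the
framework generation these settings come from — minimizing the
mean-squared error summed over the two outputs with batch size 32.

**Trainable set.** Only the added layers of both branches train; the
backbone stays frozen (its parameter checksum is asserted invariant
under training). The package does not implement partial backbone
unfreezing: gradients with respect to convolution inputs are needed
nowhere else, and the frozen-backbone reading is the only one consistent
with the added-layer topology. `model_spec(backbone_frozen = FALSE)`
errors rather than silently training something else.

**Backbones.** `"vgg16"` builds the standard 13-convolution VGG-16 stack
but requires ImageNet weights supplied as a file — a missing file is an
explicit error, never a silent random fallback. `"tiny-test"` is a small
seeded random two-convolution stack (8 and 16 filters with 4 × 4
pooling, 13 × 13 × 16 feature map) with the same interface; all tests
and the desk-scale experiments use it, so nothing needs downloading.
Random convolutional features are far weaker than pretrained ones, which
is one reason desk-scale errors should not be compared with published
clinical figures.

**Conditioning choices** (the open part of the design, decided
empirically on simulations and then frozen):

* Targets are z-scored per branch with training-set statistics and
  predictions mapped back to BPM. With raw ~100 BPM targets, the few
  hundred Adam steps of a short run cannot even traverse the output
  offset.
* Frozen backbone features are z-scored element-wise with training-set
  statistics, winsorized at ±6 SD, before entering the heads. Near-zero
  variance features (dead ReLU units) otherwise map out-of-distribution
  samples to huge activations; on one synthetic cohort a single subject
  reached a 269 BPM error through exactly this mechanism. The winsorized
  standardization removed it without touching the optimizer settings.
* With a validation set, **each branch** is restored from its own
  lowest-validation-loss epoch. The branches are independent (zeroing
  one head provably leaves the other's output unchanged), and selecting
  a single joint epoch measurably degrades whichever vital was not
  driving the joint loss.
* The number of training epochs is nowhere prescribed; the package
  defaults to 20 (10 inside the pipeline's cross-validation, where each
  of ten folds trains its own model).

## Evaluation

Pooled cross-validation follows the published protocol exactly: all kept
epochs are randomly partitioned into 10 folds (sizes within one of each
other); for each fold the remaining nine are split 75/25 into inner
training and validation, the model trains on the inner set with
best-epoch selection on the validation set, and predicts the held-out
fold. Pooling mixes a subject's epochs across folds — optimistic with
respect to subject generalization — so `evaluate_cv(group = )` offers a
subject-wise split as an option, while the pooled protocol remains the
default. Per fold and per vital the report carries MAE, Pearson
correlation (undefined and reported `NA` for constant sequences), the
Bland–Altman mean bias $\overline{y - \hat y}$, and the limit of
agreement $1.96 \times \mathrm{SD}(y - \hat y)$ with the sample
($n-1$) standard deviation. `autoplot()` draws the Bland–Altman and
scatter figures from the same per-epoch predictions.

## Problem sizes and reproducibility

The package's own experiments run at desk scale, chosen to exercise
every stage: the learning check simulates 30 subjects × 100 s (300
pooled epochs) with rates drawn uniformly over RR 15–40 breaths/min and
HR 80–180 beats/min at `noise_sd = 0.02`, trains ≤ 20 epochs, and
beats the train-mean predictor on every tested seed (typical held-out
MAE ≈ 3–9 BPM for HR and 1–3 breaths/min for RR against baselines of
≈ 22 and ≈ 5.5); the default pipeline configuration processes one 20 min
recording (120 epochs) through full 10-fold evaluation. Every random
draw flows from named seeds — two runs of `run_pipeline()` with one
configuration produce byte-identical epoch tables, images and reports on
one CPU.

## Known limitations

* Synthetic validation only: the learning results certify the pipeline's
  mechanics and the discriminability of simulated spectra, not clinical
  accuracy; the simulator's omissions (real clutter, multipath,
  occlusion, subject diversity) all flatter the model.
* The 1.25 s analysis window cannot resolve closely spaced respiratory
  and cardiac lines when HR harmonics or periodic-breathing sidebands
  fall near $f_c$; the network sees heavily smeared images by design.
* The hand-written CNN runs on one CPU thread; it is sized for hundreds,
  not millions, of epochs.
* `vgg16` inference is implemented but slow in pure R and requires an
  externally supplied weights file.
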