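# radarvitals

Simultaneous estimation of heart rate (HR) and respiratory rate (RR)
from ultra-wideband (UWB) radar baseband recordings, aimed at
unobtrusive monitoring of sleeping children. The package is written for
biomedical-signal researchers who want a complete, reproducible,
CPU-only implementation of the spectrogram-plus-transfer-learning
approach — including a physically motivated simulator, because real
bedside recordings of children are confidential and cannot be shipped.

## The method

A UWB pulse radar resolves reflections into 52 range bins of 0.0388 m;
each bin emits a 20 Hz baseband amplitude stream modulated by chest-wall
motion. The pipeline is:

1. **Movement screening.** Each 10 s epoch gets a movement score
   $S=\sum_b\sum_t |a_b(t{+}1)-a_b(t)|$; a 5-minute window is discarded
   iff more than 10 of its epochs score above 300. Per-epoch labels are
   means of the 30 in-epoch samples of the 3 Hz reference monitor.
2. **Spectrogram images.** For the 3 range bins carrying the subject,
   each epoch becomes a band-limited (0.2–4 Hz, 144 DFT rows) Hamming
   STFT magnitude block (25-sample window, hop 3, transform length 756,
   59 frames); the three blocks concatenate to a 144 × 177 image,
   min–max scaled, bilinearly resized to 224 × 224 and replicated to 3
   channels.
3. **Dual-branch regressor.** A frozen convolutional backbone (VGG-16
   with user-supplied ImageNet weights, or a small seeded `tiny-test`
   stack) feeds two identical branches — conv 3×3×16, max-pool 3×3,
   dense 8/4/1 — one predicting HR, one RR, trained with Adam
   (lr 0.005, inverse-time decay 0.001, batch 32) on summed MSE.
4. **Evaluation.** Pooled 10-fold cross-validation with an inner 75/25
   train/validation split; per fold and vital: MAE, Pearson r,
   Bland–Altman mean bias and 1.96 × SD limits of agreement.

## Worked example

```r
library(radarvitals)

sim <- simulate_recording(duration = 120, seed = 1)   # one quiet subject
ep  <- label_epochs(sim$vitals,
                    apply_exclusion(partition_epochs(sim$recording)))
ep[1:4, c("epoch", "start_s", "movement", "kept", "hr_label", "rr_label")]
#>   epoch start_s movement kept  hr_label rr_label
#> 1     1       0    103.  TRUE       110       30
#> 2     2      10     98.8 TRUE       110       30
#> 3     3      20     97.1 TRUE       110       30
#> 4     4      30    102.  TRUE       110       30

feats <- featurize_epochs(sim$recording, ep)          # 144x177 images + tensors
m <- build_vitals_model(model_spec("tiny-test"), seed = 1)
m <- train_vitals_model(m, feats, train_config(max_epochs = 10, seed = 1))
predict(m, feats[1:3, ])
#>   hr_hat rr_hat
#> 1   110.   30.0
#> 2   110.   30.0
#> 3   110.   30.0
```

Movement scores around 100 are well under the 300 exclusion threshold,
so all epochs are kept; the trained heads recover the subject's true
110 beats/min and 30 breaths/min on the training recording. For a full
cross-validated run use `run_pipeline(pipeline_config(), "out/")`, which
persists the recording (HDF5), epoch table, images, model and the
fold-by-fold agreement report, or the command-line front end:

```sh
Rscript inst/cli/radarvitals.R run --out out/
Rscript inst/cli/radarvitals.R simulate --duration 300 --hr 120 --rr 25 --out rec.h5
Rscript inst/cli/radarvitals.R filter --in rec.h5 --out epochs.csv
```

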