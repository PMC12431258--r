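# snorescreen

Two-stage acoustic screening of obstructive sleep apnea–hypopnea syndrome
(OSAHS) from overnight ambient-microphone recordings, for sleep-acoustics
researchers and engineers building non-contact snore monitors.

**Stage 1 — endpoint detection.** An adaptive multi-feature detector
segments snore events from long recordings. Per 2-minute window, 25 ms /
10 ms Hamming frames yield four features — short-time energy
`E_i = Σ x_i(n)²`, spectral entropy `H_i = −Σ P_i(k) log(P_i(k)+ε)`,
zero-crossing rate `ZCR_i = (1/2N) Σ |sgn x_i(n) − sgn x_i(n−1)|`, and
spectral centroid `C_i = Σ f·|X_i(f)| / Σ |X_i(f)|`. Thresholds adapt to
each window (`T_E` = 10th percentile, `T_C` = 75th percentile,
`T_H`/`T_ZCR` = mean + 0.5 sd) and a frame is a snore frame when at least
3 of the 4 conditions `E ≥ T_E`, `H ≤ T_H`, `ZCR ≤ T_ZCR`, `C ≤ T_C` hold.
Runs of snore frames become segments; gaps < 0.3 s merge and segments
< 0.3 s are discarded. Optional spectral-subtraction denoising
(`max(|Y(k,l)| − |N̂(k)|, 0)`, phase reuse, overlap-add) removes stationary
interference.

**Stage 2 — classification.** Each event's 128×128 log-Mel spectrogram is
classified by a hybrid network: a ResNet18 backbone with efficient channel
attention (ECA) in the two deepest stages — per-channel global average
pooling, an adaptive `k = |log₂(C)/γ + b|_odd`-wide 1-D convolution across
channels, sigmoid re-weighting — whose final feature map is unfolded along
time into a bidirectional GRU head. All ablation variants (ResNet18,
ResNet18+BiGRU, ECA-ResNet18, ECA-ResNet34+BiGRU, full model) are plain
configurations. Layers, backpropagation and Adam are implemented in the
package (Rcpp/BLAS convolution kernels); no external deep-learning
framework is required.

A seeded synthetic-audio module generates nocturnal recordings with exact
snore ground truth under presets mirroring the evaluation conditions
(near-clean `denoised`, hum + transients `original`, added low-level
chatter `speech`), plus a separable two-class spectrogram dataset for
classifier smoke training. See the methods vignette
(`vignettes/snore-analysis.Rmd`) for the model, its assumptions and the
generator's design.

## Worked example

```r
library(snorescreen)

cfg  <- snore_sim_config(duration_s = 600, preset = "denoised", seed = 1)
sim  <- synth_recording(cfg)          # 10-min night, 60 snore events
print(sim$signal)
#> <audio_signal> 9600000 samples @ 16000 Hz (600.000 s), peak 0.1425

segs <- detect_snores(sim$signal)
head(segs, 3)
#>   t_start_s t_end_s n_frames mean_vote
#> 1      1.57   6.895      531  3.994350
#> 2     11.20  16.825      561  3.998217
#> 3     21.63  27.125      548  3.994526

endpoint_accuracy(segs, sim$truth)
#> <detection_eval> f_r=60 f_a=62 accuracy=96.8% recall=1.000 missed=0 (IoU>=0.30)
```

Each row of `segs` is one detected snore interval with its frame count and
mean vote (how many of the four feature conditions held on average).
`accuracy` is the fraction of detections matching a true event at
IoU ≥ 0.3 — here 60 of 62 detections are genuine snores and every planted
event was recovered (`recall = 1`). The classical energy+ZCR detector on
the same recording scores visibly worse, missing the whistling snores:

```r
base <- detector_config(features_used = c("energy", "zcr"), vote_threshold = 2)
endpoint_accuracy(detect_snores(sim$signal, base), sim$truth)
#> <detection_eval> f_r=53 f_a=62 accuracy=85.5% recall=0.883 missed=7 (IoU>=0.30)
```

Classifier smoke training on the synthetic spectrogram dataset:

```r
ds <- synth_spectrogram_dataset(20, "easy", seed = 11)   # 40 labelled clips
tm <- train_model(build_model(model_config()), ds,
                  train_config(max_epochs = 30, seed = 5,
                               target_train_acc = 0.97))
max(tm$history$train_acc)     # reaches 1.0 within a few epochs
predict_model(tm, ds$spectrograms[[1]])
```

A thin command-line wrapper is installed under `inst/cli/snorescreen`:

```sh
snorescreen synth --out night/ --preset speech --duration 600 --seed 7
snorescreen detect night/recording.wav --out segments.tsv
snorescreen eval detect --pred segments.tsv --ref night/truth.tsv --iou 0.3
```

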