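# megdecode

Decoding spoken and imagined phrases from multichannel neuromagnetic (MEG)
signals, as a tested R pipeline. The package is aimed at researchers working
on non-invasive speech brain–computer interfaces who want a reproducible,
fully-testable implementation of a wavelet-based phrase-decoding analysis —
including a synthetic MEG generator, so every stage runs and is verifiable
without access to recordings.

## What it implements

A trial is an epoched window $[-0.5, 4)$ s around stimulus onset at 1 kHz
across ~196 gradiometer channels, with four stages: pre-stimulus rest,
perception, preparation (imagination) and production. The analysis chain:

1. **Preprocessing** — epoching, zero-phase 4th-order Butterworth low-pass
   below 250 Hz, amplitude-threshold trial rejection, channel exclusion.
2. **Band decomposition** — a 7-level Daubechies-4 multiresolution analysis
   expresses each channel as $s = d_1 + d_2 + \dots + d_7 + a_7$; the two
   finest details (125–500 Hz) are discarded as noise and the remaining
   components form the six neural oscillation bands, delta (0.1–4 Hz)
   through high-gamma (62–125 Hz), whose sum is the denoised signal.
3. **Features** —
   * RMS per (channel, band) over a stage, concatenated channel-major
     ($6 \times 196 = 1{,}176$ dimensions), with ANOVA/Tukey feature
     screening across candidate statistics;
   * Morlet CWT scalograms (64 log-spaced frequencies, 0.5–125 Hz) per
     sensor, rendered to rasters;
   * a spatial-spectral-temporal composite tiling all sensors' scalograms
     into a single 14 × 14 image, plus 100/200 ms time-shift augmentation
     (3× the data, split-leakage-proof).
4. **Decoders** — a shallow 256-unit sigmoid ANN trained by SGD with early
   stopping; a small CNN (11 × 11 stride-4 first kernel) trained with Adam,
   minibatch 64, gradient clipping and validation-event patience; and
   average-cross-entropy aggregation of per-sensor CNN outputs into trial
   decisions.
5. **Evaluation** — stratified 70/15/15 splits × 3 repeats, confusion
   matrices with per-class and average accuracy, one-vs-rest ROC/AUC, the
   exact binomial chance level
   $\min\{a : P(\mathrm{Bin}(n, 1/K)/n \ge a) \le \alpha\}$, and paired /
   one-sample t-tests (with a Holm-adjusted column as a labelled extension).

The synthetic generator plants class-specific band-limited sinusoidal
signatures (per-channel Gaussian amplitude profiles, stage-gated SNR,
reaction-time jitter, optional blink/cardiac artifacts) in $1/f$ background
noise, so decoder calibration and recovery are testable end to end.

## A worked example

```r
library(megdecode)

cfg <- synth_config(n_trials_per_class = 50, n_classes = 5, n_channels = 36,
                    stage_snr = c(pre = 0, perception = 1,
                                  preparation = 1, production = 1),
                    seed = 11)
trials <- generate_dataset(cfg)
report <- run_pipeline(trials, "production", "ann", n_repeats = 1, seed = 3)
report
#> <eval_report> ann @ production: 100.00 +/- 0.00 % (chance 34.29%, macro AUC 1.000)
```

Reading the output: with strongly separated synthetic signatures
(stage SNR 1), the RMS + ANN baseline decodes the production stage
perfectly on the held-out test set of 35 trials, whose exact binomial
5-class chance level at $\alpha = 0.05$ is 34.29% — so the result is far
above anything a random classifier would plausibly reach. On the silent
pre-stimulus stage the same pipeline stays inside the chance interval.

The bundled published confusion matrix reproduces its printed accuracies:

```r
cm <- phrase_confusion_counts()
truth <- rep(rownames(cm), rowSums(cm))
pred <- unlist(lapply(seq_len(nrow(cm)), function(i) rep(colnames(cm), cm[i, ])))
confusion_and_accuracy(truth, pred, labels = rownames(cm))
#> per-class: 96.38 / 96.82 / 96.31 / 96.74 / 97.11
#> average 96.67% | overall 96.67%
```

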