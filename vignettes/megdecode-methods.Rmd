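---
title: "Decoding phrases from neuromagnetic signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding phrases from neuromagnetic signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megdecode)
```

## The problem

Magnetoencephalography records, at millisecond resolution, the magnetic
fields produced by cortical currents across a couple of hundred gradiometer
sensors. In a delayed-reading paradigm a subject sees a phrase, silently
prepares it, and then speaks it aloud; each trial is epoched from 0.5 s
before stimulus onset to 4 s after, with four stages: pre-stimulus rest
(0.5 s), perception (1 s), preparation/imagination (1 s) and production
(about 2 s). The decoding task is five-way single-trial classification:
which of five phrases does the neural activity in a given stage encode?
`megdecode` implements the full analysis path — denoising, band
decomposition, feature extraction, three decoders, and the evaluation
protocol — together with a synthetic generator so that every stage is
testable without access to recordings.

## Synthetic MEG generator

Real task MEG is, to first order, broadband background activity with a
roughly $1/f$ spectrum, on top of which task-related band-limited
oscillations ride in specific sensors. The generator mirrors exactly that
structure:

* **Background**: independent Gaussian noise per channel, spectrally shaped
  to $1/f^{a}$ (default $a = 1$, configurable in $[0, 2]$), unit standard
  deviation. Units are arbitrary; every amplitude in the simulation is
  expressed relative to this noise floor.
* **Class signatures**: each phrase class is assigned sinusoidal carriers in
  named neural oscillation bands (carrier frequencies strictly inside the
  band, distinct per class) with smooth Gaussian amplitude profiles over the
  channel index. Channel geometry is abstract — index only, no physical
  layout.
* **Stage gating**: the signature is injected only into stages with a
  positive configured signal-to-noise ratio, defined as
  $\mathrm{RMS}(\text{signal})/\mathrm{RMS}(\text{noise})$ over the active
  segment and all channels. Defaults are `pre = 0`,
  `perception = 0.2`, `preparation = 0.3`, `production = 0.5`: weak-to-
  moderate single-trial SNRs ordered the way stage decodability is expected
  to be ordered (information builds from reading to overt articulation),
  with a silent baseline. On/offsets are Hann ramps over 10% of the segment
  so band energy does not splatter across stage boundaries.
* **Reaction-time jitter**: the production-stage signature onset is delayed
  by a truncated normal draw, mean 0.25 s, SD 0.1 s, truncated to
  $[0, 0.5]$ s — production onset follows the go cue by a reaction time of
  about a quarter second, with realistic trial-to-trial variability.
* **Carryover**: whether pre-stimulus activity should carry residual
  class information from the previous production epoch is genuinely
  unknown, so it is exposed as `carryover_gain` in $[0, 1]$ and defaults to
  0 (a clean, class-independent baseline). Raising it reproduces
  above-chance pre-stimulus decodability for anyone wanting to study that
  phenomenon.
* **Artifacts**: optional blink-like transients (Gaussian pulses, SD 80 ms,
  so spectral content sits below 4 Hz, high amplitude, frontal channel
  subset) and quasi-periodic ~1 Hz cardiac-like pulse trains, with a
  Poisson event count per trial and a complete injection log.

What the generator deliberately does **not** model: dipole forward physics,
sensor cross-talk, inter-subject anatomical variability, or any acoustic or
jaw-motion channel. Passing tests on this data therefore demonstrates that
the pipeline recovers planted spatio-spectral class structure at realistic
SNR — not that any particular accuracy would be reached on real recordings.

## Preprocessing

Trials are low-pass filtered below 250 Hz with a 4th-order Butterworth
filter. The filter is applied forward and backward (zero-phase), because
one-pass IIR filtering would delay band energy across the stage boundaries
that all later analyses key on; the effective magnitude response is the
squared single-pass response. Signals are padded with an odd reflection at
both ends before filtering so the filter transient decays in the padding
rather than inside the trial. Trial rejection approximates visual artifact
screening by thresholding: a trial is dropped when any channel's peak
amplitude exceeds a threshold (default: six times the per-channel median
absolute deviation, so the default is usable on data of any scale) or when
a channel is flat. Excluded channels are removed by id with order
preserved; all indexing is 0-based in time (seconds relative to stimulus
onset) with half-open stage intervals $[start, end)$.

## Wavelet band decomposition

The denoising/decomposition step expresses each channel as a sum of dyadic
components of a 7-level Daubechies-4 analysis: details $d_1 \dots d_7$ and
the approximation $a_7$, with $s = d_1 + \dots + d_7 + a_7$. At 1 kHz
sampling, $d_1$ (250–500 Hz) and $d_2$ (125–250 Hz) carry no neural
information and are discarded; the remaining components map to high-gamma
($d_3$), gamma ($d_4$), beta ($d_5$), alpha ($d_6$), theta ($d_7$) and
delta ($a_7$), and their sum is the denoised signal.

Implementation choice: the package computes an **undecimated**
(maximal-overlap) multiresolution analysis in the frequency domain rather
than a decimated pyramid. The undecimated transform is shift-invariant,
works for any epoch length, and its components satisfy the additive
reconstruction identity *pointwise and exactly* (the squared magnitudes of
the cascade filters telescope to one at every frequency), which turns the
reconstruction identity into a machine-precision invariant rather than an
approximate one. Signals are symmetrically extended past both ends (by the
level-7 equivalent filter support) before the circular transform and
trimmed afterwards, which is the boundary handling that least distorts a
4.5 s epoch. Band labels follow the conventional printed ranges (gamma
31–58 Hz, alpha 8–16 Hz) even though the dyadic splits sit at powers of
two of the sampling rate (gamma is physically the 31.25–62.5 Hz octave);
the printed 58–62 Hz gap — presumably a line-noise guard — cannot be
realised by a dyadic filter bank and is treated as a labelling convention.

RMS features are computed per (channel, band) over one analysis stage and
concatenated channel-major; with 196 channels the vector has
$6 \times 196 = 1{,}176$ entries. The feature screening utility runs a
per-dimension one-way ANOVA across classes (Tukey HSD for the pairwise
structure) over a candidate set of summary statistics — RMS, mean, median,
SD, quartiles, tertiles, energy, windowed energy — and ranks candidates by
the fraction of dimensions significant at $\alpha$ (default 0.001).
The cross-correlation-matrix candidate sometimes used in this literature is
omitted: its dimension grows quadratically in channels and it is not needed
by any downstream step.

## Scalograms, tiling and augmentation

Time-frequency images are Morlet continuous wavelet scalograms of the
denoised signal: squared coefficient magnitudes at 64 log-spaced centre
frequencies covering 0.5–125 Hz (at least four voices per octave across
the analysis bands), with the Morlet centre-frequency parameter fixed at
$\omega_0 = 6$ — the conventional choice balancing time and frequency
resolution. The cone of influence is derived from the wavelet e-folding
time and returned with each scalogram. Because the denoised signal has no
content above 125 Hz, scalograms are computed on a 2x decimated copy
(500 Hz), which halves the transform cost without touching the analysis
band.

Rendering maps $\log_{10}(E + \varepsilon)$ through per-image min–max
normalisation to $[0,1]$, bilinear resizing, and a fixed
perceptually-uniform colormap (viridis). Normalisation is per image — the
input convention of image classifiers — and the scalar field is resized
*before* colour mapping so interpolation never mixes RGB triples and
luminance stays monotone in energy.

The spatial-spectral-temporal representation tiles one scalogram raster
per sensor into a fixed grid (14 × 14 for 196 sensors) in ascending
channel order, row-major. No anatomical sensor arrangement is assumed —
the channel geometry is abstract throughout — and the order is recorded in
the tile map and overridable; tiles round-trip bit-exactly.

Time-shift augmentation re-windows each trial at +100 and +200 ms, tripling
the collection. Since trials store only their epoched window, the shifted
tail is zero-padded and logged. Augmented children carry provenance
(`parent_id`, `shift_ms`), inherit labels, and the split logic places them
in their parent's split; the CNN trainer independently audits the split
manifest and raises a hard error on any leakage. Pipeline evaluation is
always on original test trials.

## Decoders

**Shallow ANN.** One hidden layer of 256 sigmoid units, softmax output,
minibatch SGD (learning rate 0.01 from the grid 0.1/0.01/0.001/0.0001),
at most 100 epochs, early stopping after more than 6 consecutive epochs of
rising validation loss, best-validation snapshot returned. Features are
z-scored with training-set statistics inside the model.

**Small CNN.** A compact convolutional classifier: conv blocks (the first
with an 11 × 11 kernel and stride 4 — scalogram class information lives in
coarse energy blobs, which a large first receptive field captures well —
then 3 × 3 kernels), ReLU, 2 × 2 max-pooling between blocks, flatten, and
a fully-connected 5-way softmax head. Training uses Adam at a fixed base
learning rate of $10^{-4}$, a 20× learning-rate multiplier on the freshly
initialised head, minibatch 64, at most 60 epochs, and gradient clipping
by global norm at 1.0 (a clipping value has to be chosen; 1.0 is the
common default). Validation runs every 6 iterations and early-stopping
patience is counted in validation events. Convolution is implemented as
im2col matrix multiplication in base R with an exactness guarantee:
backpropagated gradients are tested against central finite differences.
The architecture is deliberately small enough to train on a CPU in
minutes; ImageNet-scale pretrained backbones are outside the package's
scope, and the training protocol above is the part that matters for the
method.

**Per-sensor aggregation.** The spectral-temporal variant trains on each
sensor's image as an independent sample (pooled across sensors) and makes
trial decisions by the average cross-entropy score: trial score for class
$k$ is the mean over sensors of $-\log p_s(k)$, and the predicted class
minimises it — equivalently the geometric-mean probability. Probabilities
are floored at $10^{-12}$ before the log; exact ties resolve to the lowest
class index and are flagged. An arithmetic-mean-probability alternative is
available since either reading of "average cross-entropy" is defensible.

## Evaluation protocol

Splits are stratified 70/15/15 train/validation/test by class (and
subject), repeated three times by default, deterministic under a seed.
Decoding is subject-dependent: models are trained per subject. Reported
metrics: mean ± SD accuracy over subjects × repeats; the pooled confusion
matrix with per-class accuracies (whose unweighted mean is the headline
"average" accuracy) plus trace/total overall accuracy; one-vs-rest ROC
curves integrated by the trapezoidal rule with macro-average AUC; and the
chance level.

The chance level inverts the exact binomial tail — the smallest accuracy
$a$ with $P(\mathrm{Bin}(n, 1/K)/n \ge a) \le \alpha$ — rather than using
a normal approximation, and is capped at 100%. One consequence worth
stating: at $\alpha = 0.05$ and $K = 5$, sixty trials give a 30% threshold
while three hundred give 24.3%; "about 30%" therefore corresponds to the
per-condition trial count, not the total, and the function leaves both
$n$ and $\alpha$ to the caller.

Method and stage comparisons use paired two-tailed t-tests on the
per-subject accuracy arrays, and one-tailed one-sample t-tests against the
chance threshold; pairwise tables additionally carry a Holm-adjusted
column, clearly labelled as an extension beyond the uncorrected protocol.
Degenerate zero-variance comparisons are flagged rather than erroring.

## Numerical and scale choices

* Reconstruction identity tolerance: $10^{-6}$ relative; in practice the
  implementation achieves $\sim 10^{-12}$.
* Scalogram FFTs are zero-padded to at least twice the segment length to
  limit wrap-around of long low-frequency wavelets.
* Augmented trials reuse their parent's denoised signal (the shifted
  window is sliced from it, zero-padded past the epoch end), which is both
  faster and closer to re-windowing the source recording than decomposing
  the zero-padded child.
* The bundled demonstrations and the acceptance script run at desk scale:
  5 classes × 50 trials × 36 channels for the decoder calibration study
  (the tiling grid scales with the channel count, 6 × 6 there, rendered at
  8 px per tile into 48 × 48 composites; at that input size three conv
  blocks are used so a 2 × 2 spatial map survives to the classifier head),
  with the full 196-channel geometry exercised where it is cheap (feature
  vectors, 14 × 14 tiling). These sizes were chosen so the whole study
  runs on a single CPU in minutes while keeping every statistical property
  of the full-size problem.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_trials_per_class = 50, n_classes = 5, n_channels = 36,
                    stage_snr = c(pre = 0, perception = 1,
                                  preparation = 1, production = 1),
                    seed = 1)
trials <- generate_dataset(cfg)
report <- run_pipeline(trials, "production", "ann", n_repeats = 3, seed = 1)
glance(report)
autoplot(report)
```

## Known limitations

* The generator's sinusoidal signatures are narrowband and stationary
  within a stage; real speech-related dynamics are broadband and
  non-stationary, so decoder accuracies here say nothing quantitative
  about real MEG.
* Subject-independent (cross-subject) decoding is out of scope.
* The small CNN is not a reproduction of any pretrained ImageNet
  architecture; it implements the same training protocol at a size
  appropriate for CPU experimentation.
* Band labels follow printed convention, not the exact dyadic edges (see
  above); the 58–62 Hz gap is unassignable in a dyadic bank.
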