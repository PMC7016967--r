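---
title: "Multimodal bio-sensing features for driver awareness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal bio-sensing features for driver awareness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`driversense` implements a complete analysis pipeline for studies that ask
whether wearable bio-sensing (EEG, PPG, GSR) and face video can tell how
attentive a driver is, and whether a short road event registered as hazardous.
The study design it serves has 12 subjects watching 35 driving videos each
(20 annotated as requiring low attention, 15 high; 14-105 s long), with 70
two-second incidents annotated hazardous/non-hazardous, EEG from a 14-channel
consumer headset at 128 Hz, PPG and GSR from an armband at 51.2 Hz, and
49-point facial landmarks at 30 fps. Because such recordings are rarely
shareable, the package also contains a synthetic-data generator that emulates
the statistical structure the pipeline assumes, so every stage runs and is
tested end-to-end with no external data.

# Feature extraction

## EEG: conditional entropy between channel pairs

Attention during driving engages distributed brain networks, so the first EEG
representation measures *dependence between regions* rather than local power.
For each unordered electrode pair the package computes the conditional entropy
$H(Y\mid X)$ through the mutual information

$$ I(X;Y) = \sum_{x}\sum_{y} p(x,y)\,\log_2\frac{p(x,y)}{p(x)\,p(y)},
\qquad I(X;Y) = H(Y) - H(Y\mid X), $$

estimated by the histogram plug-in rule: each channel is discretized into
`bin_count` equal-width bins over its observed range (16 by default; the
estimator itself is not prescribed by the measure, and the plug-in rule is the
simplest faithful choice), the joint histogram gives $p(x,y)$, and
$0 \log 0 := 0$. The identity above then holds *exactly* for the plug-in
quantities, which the tests assert to $10^{-9}$ bits. Because
$H(Y|X) \neq H(X|Y)$ while one value per pair is wanted, $Y$ is fixed to the
later channel of the pair in the canonical electrode order (AF3, AF4, F3, F4,
F7, F8, FC5, FC6, T7, T8, P7, P8, O1, O2). Fourteen channels give
$\binom{14}{2} = 91$ features. (Published tables sometimes quote 96 for this
feature family; the combinatorial count for 14 electrodes is 91, which is what
the package implements.)

EEG is band-pass filtered to 4-45 Hz first (4th-order Butterworth, applied
forward-backward for zero phase, odd-reflection padding at the edges). Heavy
artifact excision is out of scope; `amplitude_reject()` offers a simple
z-score threshold with linear interpolation over flagged spans.

## EEG: band-power topographic images

The second EEG representation renders the scalp distribution of theta
(4-7 Hz), alpha (7-13 Hz) and beta (13-30 Hz) power as one RGB image. Per
band: Welch PSD (1-s Hann windows, 50% overlap) averaged over the trial and
over the band, per channel; the 14 values are scatter-interpolated over the
unit head disc (inverse-distance weighting, power 2, on a 32x32 grid - the
channels are scattered points, so some scatter-to-grid rule is needed before
any image resampling), normalized by that band image's maximum, resampled to
224x224 with a Catmull-Rom bicubic kernel, and placed in the band's color
channel (theta = red, alpha = green, beta = blue). The three channels are
alpha-blended with weights proportional to each band's total power, scaled so
the strongest band has weight 1, then clipped to [0, 1] and zeroed outside
the head disc. Two consequences worth knowing: the image is invariant to a
common rescaling of all three band-power vectors, and a band with zero power
yields an identically-zero color channel. The blending rule and the
interpolation settings are configurable because the prose descriptions such
pipelines give are ambiguous; the defaults above are this package's pinned
reading.

`topomap_sequence()` produces the trend representation: contiguous
non-overlapping windows (one per second for attention-length trials; 30 per
second for 2-s incidents, giving 60 images) each rendered as above, with
sub-second windows using a zero-padded periodogram (the zero padding to 256
FFT points guarantees every band contains frequency bins even for 4-5 sample
windows).

## PPG and GSR

PPG is smoothed with a 0.25-s centered moving average, min-max scaled to
[0, 1], and peak-picked: local maxima above half the rolling 90th percentile,
thinned so no two peaks are closer than 0.5 s (the taller of a conflicting
pair wins). Heart rate is peaks per minute; pNN50 is the fraction of
successive RR differences exceeding 50 ms (reported as a fraction, per the
measure's name). Six time-domain descriptors complete the block: mean,
standard deviation, mean absolute first difference (raw and standardized),
and mean absolute second difference (raw and standardized) - so features 4
and 6 are features 3 and 5 divided by the standard deviation. GSR is smoothed
the same way; its block counts skin-conductance responses (peak height
measured from the preceding trough, separating phasic SCR from tonic level;
peaks under 0.01 units ignored) plus the same six descriptors. Spectrogram
images (Hann STFT, 4-s windows, 75% overlap, log magnitude, a
perceptually-uniform colormap, bicubic resize to 224x224) are cropped to
0-5 Hz for PPG and 0-2 Hz for GSR, the ranges where those signals live. The
STFT window, overlap and colormap are package choices - the images feed an
embedding, not human readers, so bit-exact colormap matching is irrelevant.

## Face landmarks

From each 49-point frame the package computes 30 geometric features - 22
distances between landmark-group centroids (brow-eye, brow-brow, eye
widths/heights, nose-mouth, mouth width/height, lip gap, ...) and 8 angles at
line-segment intersections. Only a few example features are ever named in
published descriptions of this feature family; the concrete list here
(`geometric_feature_specs()`) is an explicit reconstruction, and the
tests therefore pin *invariances* (translation, uniform scale, rotation for
angles, left/right symmetry) and counts rather than specific values.
Horizontal distances are normalized by the face-box width, vertical by its
height, oblique by the diagonal; angles are in radians, unnormalized. Across
a trial's frames each column is aggregated as mean, 95th percentile (more
robust than the maximum) and standard deviation - the 95th percentile uses
the linear-interpolation order statistic (R type 7), pinned for
cross-language reproducibility - giving 90 features per trial, or 3 x 4096
for embedded face images.

## Image embeddings

All three image families (EEG topomaps, PPG/GSR spectrograms, face crops)
share one contract: a 224x224x3 float image in [0, 1] maps to a
4096-dimensional vector, the width of the penultimate fully-connected layer
of the VGG networks used for transfer learning ("most significant 4096
features" is read as that whole layer; no selection). Pretrained weights do
not ship with the package: `image_embedder("vgg16")` fails with a message
naming the fallback unless an external `embed_fn` is plugged in, and the
deterministic **stub** backbone (block-mean pooling to 32x32x3, a fixed
seeded Gaussian projection to 4096, half-wave rectification) stands in so the
whole pipeline and its tests run offline. The stub preserves shapes,
determinism and Lipschitz continuity, but it is a random projection, not a
trained network - class structure that a CNN would amplify survives only
weakly, which matters when interpreting the recovery results below.

# Classification and evaluation

Features are normalized per column to [-1, 1] (min to -1, max to +1,
constant columns to 0), reduced with PCA to 30 components (60 per step for
sequence features), and classified with an extreme learning machine: a
single hidden layer of 170 units with the triangular basis activation
$\mathrm{tribas}(u) = \max(1 - |u|, 0)$, input weights and biases drawn
uniformly on [-1, 1] from a recorded seed and frozen, and output weights
solved by ridge-regularized least squares ($\lambda = 10^{-6}$, pseudo-inverse
fallback) - initialization and solver are package choices, as ELM
formulations leave them open. Scores are exposed for AUC; a score of exactly
0 goes to the positive class (+1 = high attention / hazardous).

The trend representation feeds a two-layer LSTM (200 and 100 units) trained
with SGD-with-momentum on the logistic loss of the final step's readout.
Unstated hyperparameters default to: learning rate 0.01, momentum 0.9, 50
epochs, batch 16, uniform $\pm 1/\sqrt{\text{fan}}$ initialization,
forget-gate bias +1. The backward pass is verified against finite
differences in the test suite. Ragged sequence lengths are refused - the
trend classifier requires a fixed trial duration.

Evaluation is leave-one-subject-out: for each of the 12 subjects, scaler,
PCA and classifier are fitted on the other 11 subjects' 385 trials and
evaluated on the held-out 35. Accuracy is reported per subject as
mean +/- sd; AUC is computed per fold from the continuous scores and averaged
(per-subject-averaged rather than pooled - the choice is pinned here because
either reading is defensible), with single-class folds marked `NA`.
`fit_scope = "global"` reproduces the across-subject normalization some
studies use; the default `"train_only"` avoids test-set leakage, and both are
available because the difference itself is informative. Paired t-tests and
one-way ANOVA compare fold-accuracy vectors across modalities.

# The synthetic generator

`gen_dataset()` emulates the study conditions: 12 subjects x 35 attention
trials (durations uniform on 14-50 s, spanning the two stimulus sets' ranges)
plus 70 two-second incidents per subject, with 20/35 low-attention and 30/70
hazardous labels. Class effects are injected into *physiological observables*,
never into features directly:

* **EEG** - per-channel 1/f background plus three band-limited components
  with plausible topographies (alpha posterior, beta fronto-central, theta
  frontal), each a mix of a shared source and channel noise. High-attention /
  hazardous trials scale alpha amplitude by $e^{-0.35\,\text{effect}}$ and
  beta by $e^{+0.35\,\text{effect}}$ (power roughly halved/doubled at
  effect 1); lognormal subject gains (sd 0.2) multiply on top.
* **PPG** - gamma-shaped pulses at RR intervals jittered by `hrv_level`
  (Gaussian, or alternating for an exact pNN50 = 1 construction), plus
  baseline wander and sensor noise; subject heart rates are drawn around
  72 bpm and clamped to 50-110.
* **GSR** - smooth sigmoidal tonic drift plus Poisson-timed SCRs
  (half-cosine rise, exponential decay, amplitudes 0.1-0.5).
* **Face** - the canonical symmetric 49-point face with a smooth random
  brow-raise/mouth-open time course whose amplitude grows 2.5-fold at
  effect 1 on active trials, plus 0.5 px frame jitter.

With all effects at 0 the label-conditional distributions are identical by
construction, which the moment tests verify. One global seed fans out to
per-subject/trial/modality sub-seeds, so regeneration of any single trial is
stable.

# What the tests do and do not show

The recovery experiments (and `scripts/acceptance.R`) run at the full
12 x 35 study scale. Face geometric features recover the injected hazard /
attention effect at ~90% LOSO accuracy with the effect on and stay inside
the 99% binomial chance band with the effect off; EEG band power separates
the classes with AUC ~1 on its own. Two honest caveats:

* The synthetic EEG injects its class effect into band power only, so the
  conditional-entropy features - which measure inter-channel dependence -
  carry essentially no class signal on synthetic data and score at chance
  under LOSO. They are validated structurally (counts, ordering) and against
  brute-force oracles instead. On real recordings, where attention modulates
  long-range dependence, this need not hold.
* The stub embedder dilutes the band-power signal that the topomap images
  encode (the blend weights shift with class, but a random projection does
  not amplify that), so deep-image routes on synthetic data sit near chance
  too. Swap-safety - identical shapes and pipeline behavior under stub or
  CNN backbones - is what the tests establish.

Passing tests therefore demonstrate correct mechanics and faithful recovery
of effects through the routes the generator encodes, not real-world
classification performance; headline accuracies from the original cohort are
not reproducible without the original recordings.

# Numerical choices and degenerate inputs

* Sample counts round half away from zero (51.2 Hz x 2 s = 102.4 -> 102),
  and trial slicing tolerates one sample of slack at the slowest rate so
  concatenated trials re-assemble exactly.
* Constant signals: min-max scaling refuses (zero range); the standardized
  difference statistics warn and return 0; histogram binning collapses to a
  single bin (entropy 0, no $\log 0$).
* All-zero band powers make topomap normalization undefined and are refused;
  a single zero band simply blanks its channel.
* PCA pins the SVD sign ambiguity (largest-magnitude loading positive) so
  projections are invariant to row order; `k` must not exceed
  `min(rows - 1, cols)`.
* Zero-variance paired differences report t = 0, p = 1 with a warning.
* The problem sizes used in the test suite (short trials for unit tests,
  full 12 x 35 scale for the recovery and acceptance checks) are the
  package's own balance of coverage against a laptop-friendly run time.

# Limitations

No artifact-subspace reconstruction, ICA or source localization; no face
detection or landmark localization (landmarks are consumed as input, with a
synthetic renderer standing in for camera crops); no frequency-domain HRV;
no real-device acquisition or EDF/BDF parsing; classifiers are the two the
design names (ELM, LSTM) - no SVMs or forests; binary labels only.
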