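---
title: "Single-heartbeat ECG biometrics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-heartbeat ECG biometrics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

heartprint implements a complete recognition pipeline that identifies a
person from a *single heartbeat*: a short window of ECG is cut around the
R-peak, rendered as a continuous-wavelet-transform (CWT) scalogram image,
and classified by a small residual convolutional network. This vignette
explains the scientific model behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the bundled synthetic data
can and cannot tell you about real recordings.

```{r setup, message = FALSE}
library(heartprint)
```

## Why a single heartbeat

A healthy heartbeat is a stereotyped sequence of five waves (P, Q, R, S, T).
The region around the QRS complex is both the most invariant part of the
signal within a person and the most distinctive between people, so a window
of roughly half a second centred on the R-peak carries most of the identity
information of a much longer recording. Short segments matter practically:
an authentication system that needs 10 s of contact is far less acceptable
than one that needs 0.5 s. The package therefore treats segmentation as a
first-class experimental variable — blind fixed-duration windows,
R-centred windows, and the variable-length R-R and P-P intervals — and its
phase-1 protocol sweeps all of them.

## The synthetic population

Every downstream stage is testable without data downloads because the
package generates multi-subject, multi-session ECG with exact ground truth.
Each subject is a parameter vector: per wave an amplitude $a_w$ (mV), width
$b_w$ (s) and offset $\theta_w$ (s, R at 0), plus a mean RR interval. A beat
is the sum of five Gaussian bumps
$\sum_w a_w \exp\!\big(-(t - t_k - \theta_w)^2 / 2 b_w^2\big)$, beat times
follow $t_{k+1} = t_k + \max(0.4, \text{RR} + \mathcal N(0, \sigma_{RR}))$,
and the trace receives white noise and one sinusoidal baseline-wander
component. This is a time-domain additive simplification of the classic
dynamical-system ECG simulators: it reproduces the morphological
assumptions that matter here (per-subject invariant morphology, inter-subject
differences, RR variability, session drift) while keeping closed-form
ground-truth fiducials — the exact R and P bump centres.

Defaults, chosen once for physiological plausibility: wave parameters drawn
uniformly from ranges documented in `?sample_population`; RR jitter sd
0.04 s; noise sd 0.05 mV; wander 0.1 mV at 0.33 Hz; session amplitude drift
sd 0.08 (relative). The RR lower bound is coupled to the beat span so beats
never overlap, and $\theta_P$ is constrained to lie within 245 ms of R so
the P-detector's search window always contains the truth.

What the generator does *not* emulate: electrode motion artefacts, muscle
noise, powerline interference, arrhythmic or ectopic beats, respiratory
amplitude modulation, and T-P morphology correlation. Passing tests on this
population shows the pipeline is correct and self-consistent; it does not
certify accuracy figures on real recordings.

## Preprocessing

Band-pass conditioning uses the squared magnitude response of a 4th-order
Butterworth band-pass (defaults 0.5–40 Hz), applied in the frequency domain
after odd-symmetric padding. This is the response a forward–backward
("filtfilt") pair would have, but with two advantages that matter at a
0.5 Hz corner: the phase is exactly zero (fiducials cannot shift by even one
sample) and DC is rejected exactly. Time-domain forward–backward filtering
with the available tooling left multi-second edge transients at this corner,
which is why the package filters in the frequency domain; the response is
evaluated on the warped frequency $(f_s/\pi)\sin(\pi\nu/f_s)$ so it is
smooth across 0 and Nyquist and does not ring. Filtering is idempotent to
$10^{-6}$ of signal range for mid-band content away from record edges; near
either band edge the deviation grows like $(f/f_c)^{2\,\mathrm{order}}$,
which is inherent to any non-ideal filter.

## Fiducial detection

R-peaks: candidates are local minima of a curvature proxy — the second
difference of the 10 ms moving-average-smoothed signal — that pass an
adaptive threshold, the 0.98 quantile of |curvature| over consecutive 2 s
windows (quantile thresholds make detection invariant to amplitude scale).
Each candidate is refined by a search-back, the argmax of the preprocessed
signal within ±50 ms, and candidates closer than a 250 ms refractory
interval are resolved in favour of the larger amplitude. On noise-free
synthetic records this recovers every true R with no false positives at
±10 ms tolerance, which the test suite asserts exactly.

P-peaks: for each R with a full 245 ms left context, an approximate P is the
argmax of a Hilbert (analytic-signal) envelope in the window from
$r - 245\,\mathrm{ms}$ up to a guard before R, followed by a search-back in
the preprocessed signal. The envelope signal is constructed to isolate
P-wave energy: band-pass 0.5–10 Hz, *bridge* the ±100 ms QRS region by
linear interpolation, remove the local baseline with a 250 ms moving
average, then take the analytic-signal magnitude, with a 130 ms guard
keeping bridge-edge artefacts out of the search. The bridging and the wide
guard are deliberate design choices: the naive envelope of a band-passed
ECG is dominated by QRS side-lobe energy, and the P region is actually an
envelope *minimum* — masking after the transform is not enough, the QRS
must be removed before it. With the refinement step the clean-data P error
is at most 2 ms; the detector's parameters (band, bridge width, guard) are
exposed for recordings with different P morphology.

## Segmentation and augmentation

Four schemes produce segment tables: `blind` (consecutive non-overlapping
windows from the record start, trailing remainder dropped), `r_centered`
(±window/2 around each R; boundary windows are dropped rather than padded,
because padding would fabricate morphology), `rr` and `pp` (half-open
intervals between consecutive fiducials, linearly resampled to the median
length before imaging). "Around the R-peak" is read as symmetric centring
since the informative P-through-T context flanks R on both sides.

Class balance for training uses averaging augmentation: each subject (or
each subject × session group, in session-disjoint protocols) is topped up
to 100 segments, every synthetic segment being the element-wise mean of 10
originals drawn with replacement. Averaging preserves the subject's mean
morphology while shrinking noise, which is the intended effect — the
augmented set emphasises identity over nuisance. Originals are never
altered; provenance (source row indices) is stored with every synthetic
segment, and the operation is seeded.

## CWT scalogram images

The time–frequency representation is the magnitude of the continuous
wavelet transform with an analytic Morlet wavelet (centre frequency
$\omega_0 = 6$), at 12 voices per octave over 0.5–40 Hz (matching the
preprocessing band). The transform is computed per scale in the frequency
domain after symmetric padding to at least twice the segment length, then
cropped, which keeps cone-of-influence artefacts from dominating 0.5 s
windows. The wavelet is normalized to unit peak response so the transform
is linear in the signal and a sinusoid's ridge appears at its frequency
within one voice — both asserted in tests.

Images are rendered by per-image min–max normalization, lookup in a fixed
256-entry jet-like colormap, and bilinear resizing to a square (224 px for
the reference architecture; the scaled experiments use 32 px, see below).
Min–max normalization makes images gain-invariant, which is desirable
because electrode gain is not an identity feature. Frequencies run
high-to-low from top to bottom. All choices are fixed constants, making the
imaging bit-reproducible.

## Biometric system entropy

How much identity information a representation carries is quantified by the
Kullback–Leibler divergence between the genuine-score and imposter-score
densities, $\mathrm{BSE} = \int f_G \log(f_G/f_I)$, estimated on a common
100-bin histogram grid with an $\epsilon = 10^{-6}$ density floor (the floor
keeps the integrand defined where the imposter histogram is empty).
Similarity is Pearson correlation of flattened representations; the score
function is pluggable. The package's reference experiment
(`bse_experiment()`) draws 20 subjects, cuts 100 natural R-centred beats
each (no augmentation — the entropy analysis is about the raw
representation), samples 9900 genuine and 9900 imposter pairs, and compares
the time-domain BSE with the CWT-image BSE.

An honest caveat documented here because it is easy to over-read: when the
two score distributions barely overlap — which happens on clean synthetic
data, and especially when a population draw contains two subjects with
near-identical parameters — the floored discrete KL saturates and its
comparison between representations becomes noise. The expected direction
(CWT above time domain) holds for most population draws but not all; the
reference experiment pins a seed (42) and the vignette advises treating the
comparison as directional evidence, not as a calibrated effect size.

## The small residual CNN

The classifier is a 27-layer network: a 7×7×32 convolution stem with 2×2
max pooling, ReLU and batch normalization; a residual stage at 32 channels
whose shortcut is the identity; two downsampling residual stages at 64 and
128 channels whose shortcuts are strided 1×1 projection convolutions
followed by 2×2 max pooling ("the max-pooling layer as a skip connection");
global max pooling; and a fully connected softmax classifier. With 100
classes this counts 324,068 learnable parameters — about 324 K, two orders
of magnitude below the transfer-learning baselines it is compared against.

Two printed-table ambiguities had to be resolved. The published layer table
lists the first residual downsampling stage's addition at 57×57×64 while
its own strides give 29×29; every size printed *after* that row (29×29 at
the stage's batch norm, 15×15 and 8×8 in the last stage) is consistent with
both main-path convolutions using stride 2 and the projection shortcut
using stride 2 followed by the stride-2 pooling. The implementation
therefore keeps the printed strides and reads the single addition row as a
typo. Channel counts printed as "28" in the last stage are read as 128 (the
preceding convolution outputs 128 channels). Neither choice affects the
parameter count, which is stride-independent.

Because no deep-learning framework is available in this stack (and because
the network is the package's own contribution), the training engine is
implemented in R on BLAS matrix products: im2col gather plans turn each
convolution into one matrix multiplication per batch; max pooling,
batch normalization (training and inference modes with running moments),
residual additions, global max pooling and the softmax cross-entropy head
all have hand-derived backward passes, verified against central finite
differences to relative error below $10^{-8}$ during development. Training
is plain SGD with momentum; the reference recipe is momentum 0.9, batch
150, learning rate 0.001, 80 epochs. He-style initialisation and per-epoch
shuffling are seeded, making runs bit-reproducible.

The input layer accepts any square size whose stage arithmetic stays
consistent (224, 64, 32 all work; global max pooling makes the parameter
count size-independent). The scaled experiments use 32 px images, batch 50
and 10 epochs so a full two-scheme, two-fold sweep finishes in minutes on
one CPU; the vignette states these sizes as the package's desk-scale
experiment design.

## Evaluation protocol

Phase 1 sweeps segmentation schemes and window lengths with stratified
k-fold cross-validation (per-class round-robin dealing after a seeded
shuffle). Phase 2 evaluates the winning choice in three session scenarios:
single (first session only), mixed (sessions pooled before splitting) and
multisession (train on one session group, test on the other, swap, average
— the only scenario that reveals template aging; single-session subjects
fall back to a seeded random halving). Phase 3 derives identification and
verification analyses from the multisession predictions: per-subject
accuracies, their Fisher-Z population summary (accuracies are clamped to
$1 - 10^{-6}$ before atanh, since perfect subjects do occur), the
cumulative accuracy distribution, pooled one-vs-rest confusion counts, and
FRR/FAR/TAR/TRR with the half total error rate HTER = (FRR + FAR)/2 —
used in place of an equal error rate because classifier decisions, unlike
matcher scores, cannot be threshold-swept. The McNemar test with continuity
correction $(|b-c|-1)^2/(b+c)$ is applied to the discordant counts, taken
as $b = FP$, $c = FN$ of the pooled verification confusion (an
interpretation: the pairing of discordant decisions is not otherwise
defined for pooled counts); the statistic is defined as 0 when $b = c = 0$.

No separate verification model is trained: verification is derived from the
classification results by one-vs-rest collapse, which is how the three-phase
protocol defines it.

## Numerical and degenerate-input choices

* Indices are 1-based (idiomatic R); windows are half-open `[start, start+n)`.
* All-equal scalograms render as a single colormap colour rather than erroring.
* Constant representations get similarity 0 (correlation is undefined for
  zero variance).
* Ties in the classifier's argmax resolve to the lowest class index.
* Every stochastic operation (population draw, augmentation, pair sampling,
  fold assignment, initialisation, shuffling) takes an explicit seed and is
  reproducible bit-for-bit.

## Known limitations

* The synthetic population is optimistic: real multisession recordings drift
  in ways the drift model does not capture, so accuracies on this data are
  upper bounds, not forecasts.
* The KL comparison saturates on well-separated score distributions (above).
* The CNN engine is CPU-oriented; 224 px training at the reference recipe is
  possible but slow, and the desk-scale experiments run at 32 px.
* WFDB support covers the common text-header + 16-bit format; exotic WFDB
  formats are out of scope.
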