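---
title: "Wingbeat analysis: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wingbeat analysis: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeat)
```

Weak-flying insects — aphids and small beetles a few millimetres long — are
effectively silent in flight, yet opto-acoustic sensors can record the shadow
their wings cast in an LED beam as a ~0.6 s amplitude trace. This package
turns such traces into species classifications through an explicit,
inspectable processing chain: amplitude standardization, silence trimming,
background filtering, trend removal, extraction of 52 bioacoustic features,
and balanced random-forest classification. This vignette documents the
models behind each stage, the parameters that matter, the numerical
decisions taken where the procedure was genuinely open, and what the
synthetic-data tests do and do not establish.

## The signal model

A recording is modelled as

$$a(t) = g(t) + e(t)\sum_{k=1}^{K} A\,\delta^{k-1}\sin(2\pi k f_0 t + \phi_k) + \varepsilon(t),$$

where $f_0$ is the wingbeat (fundamental) frequency, $\delta \in (0,1]$ the
harmonic decay, $e(t)$ a flight envelope, $g(t)$ a slow movement trend
(typically a single peak and trough, attributed to whole-body manoeuvres
such as banking), and $\varepsilon(t)$ background noise. The pipeline's job
is to isolate and summarize each component: stage-1/2 features describe
flight energy of $a$, stage-3 features its spectrum, stages 4–6 repeat these
on the detrended signal $\tilde a = a - \hat g$, and stage 7 estimates
$f_0$ from the autocorrelation of $\tilde a$.

## Amplitude units

Raw signed $b$-bit PCM samples are divided by $0.5 \cdot 2^b$, giving
*arbitrary amplitude units* (AAU) in $[-1, 1]$. Recordings digitized at
different bit depths thereby share one amplitude scale. Unsigned 8-bit WAV
data are re-centred before scaling; sample rate and bit depth always come
from the container header, never from assumptions.

## Trimming and the temporal outlier rule

Sound below **0.0061 AAU** is treated as background. Because noise is
stochastic, the first sample above threshold need not mark the flight:
among the supra-threshold sample *indices*, any index lying more than
**3 interquartile ranges** beyond the upper or lower quartile (type-7,
linear-interpolation quantiles) is discarded as stochastic, and the
recording is trimmed to the span of the survivors — the whiskers of a
boxplot drawn on the time axis. Trimmed spans shorter than **128 samples**
are excluded from feature extraction. (Equivalent statements of this
minimum in seconds are ambiguous across sources at different sample rates;
the package defines it in samples.) The threshold applies to $|a(t)|$,
i.e. symmetrically about zero.

## Background filtering

The trimmed signal is decomposed into 128-sample Hann-windowed frames at
50% overlap (a periodic Hann, so plain overlap-add reconstructs the
interior exactly), each frame's magnitude is reduced by a noise floor
(clipped at zero, phase preserved), and the signal is resynthesized.

The floor is a pluggable strategy. The default takes **each frame's median
magnitude across its 65 frequency bins**: a wingbeat tone and its harmonics
occupy only a few bins, so the across-bin median measures the broadband
background and subtracting it flattens noise while preserving the harmonic
peaks (verified to retain a pure tone's band energy to well over 90%). The
alternative per-bin median *across frames* is also available, but it
removes everything temporally stationary — including a persistent wingbeat —
and is appropriate only when the foreground is intermittent.

## Detrending

The trend $\hat g$ is a penalized thin-plate regression spline of amplitude
on time (index rescaled to $[0,1]$ for conditioning only), fitted with
`mgcv` under generalized cross-validation. The basis dimension is
$k = \max(10, \lfloor n/50 \rfloor)$, with two caps:

* $k \le n - 1$ for degenerate, tiny inputs;
* $k \le 2 \cdot 50\,\mathrm{Hz} \cdot d$ for a signal of duration $d$
  seconds.

The second cap is a deliberate numerical choice. A basis of dimension $k$
can track roughly $k/2$ cycles, i.e. oscillations up to $k/(2d)$ Hz — and
under the bare $n/50$ rule that ceiling is $sr/100$ Hz *for every* $n$, so
at 10 kHz any wingbeat below ~100 Hz is representable by the "trend" and a
cross-validated fit will absorb it (the tone genuinely reduces residual
error, so no smoothness criterion declines it). Flight-movement trends
occupy a few hertz; anything above the 50 Hz body-oscillation band belongs
to the wingbeat. Capping the basis at 50 Hz makes absorption structurally
impossible while leaving ample resolution for the one-or-two-cycle trends
actually observed. `max_trend_frequency = Inf` restores the bare rule.

The decomposition is exact by construction: $a = \hat g + \tilde a$ sample
by sample. If the smoother fails numerically the recording's stage-4–7
features become missing values rather than sentinels.

## The 52 features

`feature_schema()` is the single source of truth: 25 features on the
trimmed audio (6 energy statistics, 2 envelope summaries, 4 bioacoustic
band indices, 2 entropies, the dominant frequency and 10 harmonic peaks),
27 on the detrended signal (the same set, plus the trend's own amplitude
range), and the autocorrelation fundamental — 52 in all. Natural-log and
square-root storage transformations follow the schema and are applied at
storage time, because both the ANOVA and the classifier operate on the
transformed scale; `NA` marks every undefined computation (e.g. the log of
a zero amplitude range).

Numerical conventions:

* **Envelope.** The Hilbert amplitude envelope is the modulus of the
  analytic signal, computed by one-sided FFT doubling. Envelope and
  spectral features are computed on the signal zero-padded to 8192
  samples; longer signals are left unpadded rather than truncated.
* **Entropies.** Temporal, spectral and acoustic entropies are Shannon
  evenness indices on unit-sum normalizations with $0\log 0 := 0$; the
  acoustic entropy is the product of the other two, so all three live in
  $[0, 1]$.
* **Spectrum.** The mean spectrum averages the magnitudes of
  non-overlapping 128-sample Hann windows of the padded signal (64 frames),
  giving bins every $sr/128$ Hz. At 10 kHz that is 78 Hz per bin: harmonic
  *peak* features are therefore coarse, and closely spaced harmonics can
  merge into a single spectral ridge with no local maximum between them.
  Species-level hertz precision comes from the autocorrelation estimator,
  not from the spectrum.
* **Peaks.** Harmonics 1–10 are the frequencies of the ten tallest strict
  local maxima of the mean spectrum, in descending height order, ties
  broken toward lower frequency; the dominant frequency is the tallest peak
  strictly above 50 Hz, which can differ from the first harmonic when
  trend residue peaks below 50 Hz.
* **Fundamental.** Peaks of the normalized autocorrelation of the
  detrended signal are required to be at least 10 samples apart and at
  least 0.2 tall; $f_0$ is the inverse lag of the first (smallest-lag)
  qualifying peak, and estimates outside 20–2000 Hz are rejected as
  missing. Two choices here are deliberate. First, peaks are located on the
  *signed* autocorrelation: for any strongly periodic signal the modulus
  turns the negative lobe at half the period into a local maximum, so a
  modulus search reports the octave (a pure 120 Hz tone at 10 kHz would
  yield lag 42 instead of 83). Second, the 0.2 height floor gives noise a
  rejection path: white noise has no qualifying peak and the feature is
  missing, rather than an arbitrary number.

## Balanced random forests

Class imbalance in field corpora is extreme (the study ratio spans
3323 : 113). Each tree of the forest is therefore grown on a bootstrap
containing a *configured number of draws per class* (with replacement) —
the balanced bootstrap. `randomForest`'s stratified sampler implements the
draw, and `inbag_class_counts()` audits it: every tree's in-bag class
counts equal the configuration exactly. Defaults are 1000 trees and 10
variables per split. The tuned per-class sizes for the six study species
ship as `class_size_preset()`; for synthetic corpora the default resamples
every class at the smallest class count.

Missing values are imputed by per-feature *training* medians — validation
rows are filled from training statistics, never their own — or, optionally,
incomplete observations are dropped. Performance is reported per class as
TPR, TNR, weighted accuracy $0.5\,\mathrm{TNR} + 0.5\,\mathrm{TPR}$ and
class error $1 - \mathrm{TPR}$, plus each observation's maximal class
probability (its winning vote fraction), which is systematically lower for
misclassified observations. Permutation importance is reported per class;
the overall mean decrease in accuracy is defined as the *unweighted* mean
of the per-class values, so rare classes count equally.

Open-set behaviour is characterized by leave-one-species-out: retrain
without one species, predict its observations, and summarize which known
classes absorb it and with what certainty.

## Feature sets

Sets 1–5 derive from the schema (all 52; the 25 raw; the 27 detrended; the
20 harmonic-peak frequencies; the harmonics plus bioacoustic indices,
spectral entropies, dominant and fundamental frequencies — the acoustic
entropy is excluded from set 5 as a mixed time–frequency product). Sets
6–8 are data-driven: features are standardized, complete-linkage
hierarchical clustering is run on $1 - r$ (Pearson correlation, pairwise
complete; absent overlaps treated as uncorrelated), the tree is cut into
3, 5 or 14 groups, and each group is represented by the member closest to
the group centroid in standardized observation space, ties broken
alphabetically. Standardization before correlation makes the clustering
invariant to feature scaling. Clustering uses all supplied rows (training
data in the comparison workflow).

## Per-feature inference

Each feature is modelled as
`feature ~ temperature + humidity + species` on its stored scale, with
Type II F tests: each term's F measures dropping it while retaining the
others, so the species test is covariate-adjusted and invariant to
covariate order. Rows missing the feature or a covariate are dropped per
feature; p-values are reported raw by default (a Holm option exists).
Covariate-adjusted species means predict at the sample-mean covariates and
back-transform — the exponential of a mean log is the geometric mean —
while species medians come directly from back-transformed observations.

## The simulator, and what the tests show

`simulate_recording()` draws flight duration and $f_0$ from a species
template, synthesizes the harmonic tone under a raised-cosine envelope
(10 ms ramps), adds a single peak-and-trough trend confined to the flight,
places the flight inside a 0.6 s buffer at 10 kHz with sub-threshold
margins, adds Gaussian noise (default RMS 0.0015 AAU, a quarter of the
silence threshold), and quantizes to 16 bits. Envelope shape and uniform
random phases are the simplest structure that exercises every feature; they
are not biomechanical claims. Template presets use the study's
covariate-adjusted wingbeat frequencies (104–139 Hz), the printed short
flights of *P. chrysocephala* (0.076 s vs 0.17 s), a 3 Hz within-species
SD, and recording counts in the observed imbalance ratio.

Problem sizes in the test suite are chosen for desk scale: the separable
six-class corpus uses 80 recordings per class (480 in total, a 1/10-scale
corpus comparable to scaling the study's imbalance preset), f0-recovery
checks use 100 recordings per template, and the acceptance script runs the
full study shape at 490 recordings.

What passing tests show: the trimming rule matches its brute-force oracle
exactly; entropies hit closed forms; the balanced bootstrap is exact; the
wingbeat frequency is recovered to sub-hertz median error; a withheld
clone species is absorbed by its source class. What they do **not** show:
real corpora carry species differences in energy, envelope shape and
harmonic content that the simulator does not emulate (synthetic species
differ mainly in $f_0$ and duration), so synthetic species-level error
rates are *worse* than real ones where frequencies are close, and the
relative importance of non-frequency features on real data cannot be
inferred from synthetic runs. Sensor artefacts, multi-flight recordings
and "frozen flight" are likewise out of the simulator's scope.

## Known limitations

* Mixed-sample-rate corpora are rejected rather than resampled.
* The spectrum's 78 Hz bins (at 10 kHz) make harmonic-peak features coarse;
  they are retained for fidelity to the feature definitions, not for
  precision.
* The first-peak autocorrelation rule can occasionally lock onto a spurious
  early peak in low-SNR recordings (a fraction of a percent of synthetic
  runs), inflating $f_0$; such outliers are visible as gross errors rather
  than silent bias.
* No segmentation of multiple flights within one recording; the trimmer
  assumes one flight per trigger.
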