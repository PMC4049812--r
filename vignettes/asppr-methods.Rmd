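---
title: "Advance seizure prediction by pre-ictal relabeling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Advance seizure prediction by pre-ictal relabeling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asppr)
```

## The problem and the pipeline

For a patient with focal epilepsy, intracranial EEG around seizures carries
statistical structure that precedes the clinical onset. `asppr` builds
patient-specific models that answer a sharply posed question: *will seizure
onset occur between N and N+5 minutes from now?* One model is trained per
horizon N = 0..20 minutes. The pipeline is:

1. **Instances.** Each one-hour "ictal file" (6 channels at 256 Hz,
   straddling one seizure) is converted into one feature vector per 5 s,
   yielding 720 instances of 34 features x 6 channels = 204 features.
2. **4-state labels.** Instances are `ictal` (within the marked seizure),
   `pre-ictal` (the 300 s before onset), `post-ictal` (the 300 s after
   offset) or `inter-ictal` (everything else). Windows are half-open
   `(lo, hi]`: the instance whose window ends exactly at onset is the last
   pre-ictal one, so a 3600-s file with a 180-s seizure has exactly
   60/36/60/564 pre/ictal/post/inter instances.
3. **Horizon relabeling.** The t = N dataset is the t = 0 dataset with the
   instances in `(onset - 60N, onset]` removed and those in
   `(onset - 60(N+5), onset - 60N]` labeled pre-ictal (12N removed and
   12 min(N, 5) relabeled per seizure when the windows fit the file).
   N = 0 is the identity.
4. **Feature selection.** Multi-class ReliefF, run 10 times, mean weights,
   top 14 of 204.
5. **Learning.** A class-weighted one-against-one soft-margin RBF SVM with
   (C, gamma) chosen by stratified 10-fold cross-validated accuracy on the
   training split.
6. **Evaluation.** 70/30 stratified splits, 10 repeats; Sensitivity,
   Specificity and their harmonic mean (S1) on the pre-ictal vs
   non-pre-ictal collapse of the 4-state predictions, compared against
   closed-form baseline and random predictors.

## Features

Per channel, windows always *end* at the instance timestamp. Three window
roles are used: the 5-s instance window (1280 samples at 256 Hz), the
short-term window STE (9 s, 2304 samples) and the long-term window LTE
(180 s, 46080 samples). For ticks earlier than a full window the feature is
computed over all samples available up to the tick (growing-window warm-up);
this is the minimal reading consistent with exporting instances from
t = 5 s onward, and it leaves no missing values anywhere in the matrix.

| group | codes | notes |
|---|---|---|
| signal energy | `se`, `ste`, `lte` | mean squared amplitude over 5 / 9 / 180 s |
| accumulated energy | `ae` | running sum of `se` plus a per-file offset |
| wavelet band energy | `dwt1..dwt4` x {STE, LTE} | Daubechies db4, level 4 |
| nonlinear dynamics | `lyap`, `cdim` | over the 5-s window |
| moments | mean, skewness, kurtosis x {STE, LTE} | kurtosis is non-excess |
| spectral band power | `sbp1..sbp5` x {STE, LTE} | 0.5-4, 4-8, 8-13, 13-30, 30-48 Hz |
| spectral edge | SEF-50, SEF-90 x {STE, LTE} | from 0.5 Hz |

**Accumulated energy.** `AE(q) = offset + sum(E(1..q))` with one offset per
file, drawn uniformly from `[0, 10 x median(se)]` under a per-file seed. The
offset models the unknown energy accumulated before the file starts; it is
shared across channels.

**Wavelet band energies.** The nominal target bands 0-12.5 / 12.5-25 /
25-50 / 50-100 Hz are not realizable dyadically at 256 Hz (they correspond
to a 200 Hz rate). The package performs the stated level-4 Daubechies
decomposition, whose sub-bands at 256 Hz are 0-8 (approximation), 8-16,
16-32, 32-64 and 64-128 Hz, and maps them onto the four nominal labels by
merging the two lowest (approximation + coarsest detail). The transform is
the periodized orthogonal pyramid, so the reconstructed sub-band signals sum
to the input at machine precision; each whole channel is decomposed once and
the windowed mean-square energy is then taken over the reconstructed band
signals, so broadband and band energies share one windowing convention. db4
is used because the wavelet order is conventionally unstated; it is the
common default for EEG. Signals are zero-padded to a multiple of 16 and
trimmed after reconstruction, which preserves exactness on the original
support.

**Spectral estimation.** Band powers and edge frequencies come from a
Hann-tapered periodogram of the window (one-sided, density-scaled). SEF-X is
the lowest frequency bin F such that X% of the power in 0.5 Hz-Nyquist lies
within 0.5 Hz-F. A window with zero spectral power returns 0.5 Hz with a
degenerate flag.

**Nonlinear features.** The largest Lyapunov exponent uses the
nearest-neighbour divergence construction: delay embedding (dimension 10,
delay 4 samples, Theiler exclusion 20 samples), nearest neighbour per
reference point, and a least-squares slope of the mean log separation over
the first 8 forward steps, in nats per sample. The correlation dimension is
the slope of the log correlation integral against log radius over the
scaling region (radii with at least 10 admissible pairs and unsaturated
counts), with 12 log-spaced radii spanning the embedded-point distance scale
`~ sd(x) * sqrt(2 * dim)` — radii proportional to `sd(x)` alone collect no
pairs at embedding dimension 10. Both estimators cap the quadratic-cost
searches at 400 uniform-stride reference points per window; divergence
tracking still uses the full-resolution trajectory. These defaults are
stable at the 1280-sample window and are configurable via
`feature_config()`.

**Degenerate windows.** Zero-variance windows return 0 (with a flag on the
standalone operations) for skewness, kurtosis and the nonlinear features,
keeping the matrix dense for the SVM.

## Feature selection

ReliefF assigns each feature a weight by repeatedly sampling an instance,
finding its k nearest hits and, for every other class, k nearest misses
(Manhattan distance on min-max scaled features; distance ties break toward
the lower row index), and accumulating the standard multi-class update in
which each miss class contributes proportionally to its prior over
`1 - prior(own class)`. Defaults are k = 10 neighbours and
m = min(n, 1000) sampled instances — conventional values, since the source
method prints neither. Ranking averages the weights of 10 independent runs;
exact mean-weight ties break toward the lower column index; the top 14
features are kept so model quality is attributable to selection rather than
subset size.

Selection runs on the *full* t = 0 dataset by default, matching the
published ordering in which selection precedes the 70/30 split. This leaks
test instances into selection: on label-shuffled data the selected features
retain chance correlations with the shuffle and measurably inflate test S1
above the exact chance level (the package's null-property test quantifies
this at its scaled conditions). `experiment_config(relieff_scope =
"train")` restricts selection to one stratified 70% subset instead;
because evaluation repeats draw their own splits, this reduces but does not
eliminate the overlap.

## Learning module

Class weights are `1` for inter-ictal and `count(inter)/count(c)` for the
other classes, equalizing each class's total penalty mass. One binary
soft-margin RBF SVM is trained per unordered class pair (6 models for 4
classes) with per-class penalty `C x weight`; the quadratic programs are
solved by libsvm (through e1071) at tolerance 1e-3, while the one-vs-one
construction, weighting, voting and tie-breaking are the package's own.
Prediction is by majority vote, ties resolved toward the class most
frequent in training, then canonical class order. Doubling all class
weights is exactly equivalent to doubling C, which the tests use as a
consistency check on the weighting path.

The hyperparameter grid is C in {2^8, 2^12, 2^16} x gamma in {2^0, 2^2,
..., 2^10} (18 combinations), scored by stratified 10-fold cross-validated
accuracy on the training split; score ties prefer smaller C, then smaller
gamma. Stratification is by the 4-state label — without it the scarce
pre-ictal class regularly starves folds; if the rarest class has fewer
instances than folds, the fold count is reduced with a warning. Features are
z-scored with parameters fitted on the training split only. Tuning is
repeated per (horizon, repeat); the source protocol is ambiguous between
per-trial and per-horizon tuning, and per-trial is the conservative reading
of "at the start of each individual experiment".

## Evaluation

With `N(c1 -> c2)` the test-set count of class-c1 instances predicted c2 and
`P(c)` the count predicted c, the reported measures are Accuracy
(4-state percent correct) and, in the default "paper" convention,

- Sensitivity = 100 N(pre -> pre) / P(pre),
- Specificity = 100 sum over non-pre c1, c2 of N(c1 -> c2) / sum of P(non-pre),
- S1 = harmonic mean of the two.

These condition on the *predicted* class (Sensitivity here is what is
usually called precision). The printed reference values for the
frequency-matched ("informed") random predictor — Sensitivity 8.33,
Specificity 91.67, Accuracy 63.0, S1 15.2 (truncated) at class frequencies
0.7833/0.08333/0.05/0.08333 — follow from this convention. The p = 0.5
random predictor's 50/50/50 profile and the always-pre-ictal predictor's
100/0/0 profile instead require the standard truth-conditioned definitions,
so both conventions are implemented (`convention = "paper"` / `"truth"`)
and the model reports default to the printed equations. Any measure with a
zero denominator returns 0 with a degenerate flag rather than NaN, keeping
S1 defined for pathological predictors. One stated reference value is
internally inconsistent: an always-pre-ictal predictor is quoted at 5%
accuracy, but the printed frequencies give 8.33%; the package computes from
the frequencies.

Expected baseline metrics are closed-form under label/prediction
independence; the test suite confirms them by Monte-Carlo simulation
(averaging metrics over ten independent 100,000-draw trials, so the
estimator noise is well under the half-point comparison band).

## Synthetic records

The generator emulates only the statistical structure the pipeline relies
on, not physiological EEG. Background per channel is a shared latent AR(2)
source plus independent AR(2) noise (unit-normalized, scaled by `noise_sd`)
and a 10 Hz alpha oscillation with a per-channel phase; the shared source
mimics focal/extra-focal channel similarity with no extra parameters.
During the seizure the signal is amplified about 4x and a large 3 Hz
rhythmic component is added. With `preictal_effect = e > 0`, the 300 s
before onset carry a linearly graded alpha-band gain `1 + e * ramp` and a
mean shift `0.5 * noise_sd * e * ramp`, exercising both spectral and moment
features; `e = 0` makes pre-ictal windows statistically indistinguishable
from inter-ictal ones, which the tests check with a two-sample rank test on
alpha-band power. Artefacts are square 25-sigma transients. Identical
configurations and seeds yield bit-identical records; patients derive
per-file sub-seeds deterministically from one master seed.

Defaults follow the source data description: 3600-s files at 256 Hz, 6
channels, one 180-s seizure at mid-file with full 5-minute neighbourhoods.
What the generator does *not* emulate — nonstationary background drift,
infraslow modulation, channel-specific seizure morphology, realistic
artefact taxonomies — bounds what passing tests show about real data: they
validate the bookkeeping, the estimators and the learning machinery, not
clinical performance.

## Numerical and scale choices

- Artefact handling defaults to linear interpolation (duration-preserving),
  because the 5-s instance clock is aligned to wall time; excision (with
  annotation shifting) is available via `policy = "excise"`. Artefacts
  overlapping a seizure are an error — ictal ground truth is never removed.
- The property and pipeline tests run at reduced problem sizes chosen to
  exercise every code path: 10-30-minute records, one- or two-file
  patients, single-point or two-point hyperparameter grids, 2-5 repeats.
  The acceptance checks that concern exact bookkeeping use full one-hour
  records and the complete 204-feature suite.
- The pipeline's parameter-recovery check uses two 1800-s single-seizure
  files with a strong pre-ictal effect (e = 5); at that layout the
  pre-ictal base rate is 1/6, and the label-shuffle null is compared
  against the informed-random S1 at the dataset's own class frequencies.
- Instances from overlapping LTE windows are temporally correlated, so
  random splits overestimate generalization; `split = "blocked"` holds out
  a contiguous tail instead, at the cost of a class-imbalanced test block.

## Known limitations

- Feature selection before splitting (the published ordering) leaks test
  information; see above.
- The nominal wavelet band labels differ from the dyadic bands actually
  realizable at 256 Hz; the mapping is documented but band-labelled results
  are not comparable across sampling rates.
- Lyapunov and correlation-dimension estimates at 5-s windows are
  short-series estimates with subsampled neighbour searches; they are
  stable features for classification, not precise invariants.
- Inter-ictal (seizure-free) files are read but not modelled; the pipeline
  consumes ictal files only.
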