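---
title: "Detecting sleep-apnea events from inter-band EEG energy ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep-apnea events from inter-band EEG energy ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneaband)
```

## The problem and the model

Obstructive sleep apnea interrupts breathing during sleep; each event is an
annotated interval (onset, duration) on a polysomnography timeline.
Detecting individual events *within one patient's night* is harder than
separating patients from controls, because every frame comes from the same
brain under the same electrodes — only the breathing state differs.

The detector in this package rests on a single physiological observation:
during sound sleep the EEG concentrates its power in the low-frequency
bands, while the micro-arousals accompanying apnea shift relative power
toward the high bands. Formally, a 10 s frame of the channel-averaged EEG
is decomposed into the five classical bands — delta (0.25–4 Hz), theta
(4–8), alpha (8–12), sigma (12–16), beta (16–40) — and each band's energy
is

$$E_p = \sum_{n=1}^{N} x_p[n]^2,$$

where $x_p[n]$ is the band-limited signal and $N = 1280$ samples at
128 samples/s. The classification feature is not the band energy itself —
absolute energy varies erratically from frame to frame — but the
**inter-band energy ratios** $R_{pq} = E_p / E_q$, which cancel the common
gain. All ten ordered pairs form the full feature vector
(`delta_theta`, …, `sigma_beta`); the five low-over-high ratios
(`delta_theta` … `theta_alpha`) form the reduced set, which carries most
of the discriminative signal at half the dimensionality.

Frames are classified by a $K$-nearest-neighbour rule under **cosine
distance** (the scale-free geometry matches the ratio features; Euclidean,
cityblock and correlation distances are available for comparison), and
evaluated by leave-one-out or stratified $M$-fold cross-validation with
sensitivity, specificity, accuracy, ROC AUC and the geometrical
separability index (GSI) — the fraction of points whose nearest neighbour
shares their label.

## Pipeline and parameters that matter

`average_channels` → `segment` → `label_frames` → `balance_frames` →
`preprocess_frame` → `featurize` → `cv_predict` → metrics.

| parameter | default | units | why |
|---|---|---|---|
| sampling rate | 128 | samples/s | the rate of the target recordings |
| frame duration | 10 | s | shorter than the minimum event (10–25 s), so a frame can hold a single breathing state |
| guard distance | 30 | s | a non-apnea frame must be this far from every event; the original protocol never states its non-apnea sampling rule, so this is exposed as configuration |
| K | 5 | neighbours | performance is reported as flat over a wide range of K; 5 is a conventional odd default and the CLI sweeps it |
| distance | cosine | — | scale-invariant; the method's stated choice |
| CV scheme | leave-one-out | — | the primary published protocol; m ∈ {2, 5, 10} reproduces the comparison grid |

Per-frame preprocessing subtracts the frame mean and divides by the
maximum absolute value of the mean-removed frame. "Maximum sample value"
is ambiguous in prose; using the maximum *absolute* value keeps the output
in $[-1, 1]$ and sign-symmetric. Since the energy ratios are already
scale-invariant, this choice only matters for numerical conditioning.

## Numerical choices

**Brick-wall filtering.** Band splitting zeroes FFT bins outside the band
and inverse transforms, with no taper: edge ringing of the ideal filter is
part of the method. Bin assignment is half-open $[lo, hi)$ on exact bin
frequencies, so the shared printed edges (4, 8, 12, 16 Hz) are never
double-counted and band energies are additive (Parseval) to $10^{-9}$
relative. At $f_s = 128$ and $N = 1280$ the resolution is 0.1 Hz and
0.25 Hz falls between bins; delta's lowest kept bin is 0.3 Hz. A
`nearest` edge rule (snap edges to the closest bin first) is available.
The masked spectrum is conjugate-symmetric by construction; the inverse
transform's imaginary residual is asserted below $10^{-10}$ of the input
norm and discarded.

**Zero-energy bands.** A band energy of exactly zero means a flat or
broken frame, so `energy_ratio` raises rather than clamps; fabricating a
finite ratio silently would corrupt a feature matrix. For batch
robustness `featurize(floor_zero = TRUE)` floors energies at
$10^{-12}\times$ the frame energy.

**Ties.** KNN distance ties break toward the lower training index; vote
ties (even $K$) break toward apnea, favouring sensitivity — both
configurable, neither claimed to reproduce an unstated original policy.
The GSI uses Euclidean distance by default (the index's source does not
name one) with self excluded and the same lower-index tie rule; any of the
four distances can be selected.

**AUC.** Mann–Whitney with ties counted one half, which equals the
trapezoidal area under the empirical ROC and handles the discrete
$(K+1)$-level score grid of a KNN exactly.

**Aggregation.** Across subjects: arithmetic mean, sample ($n-1$) SD, and
IQR from *type-5* (midpoint plotting position) quantiles. Type 5 is
MATLAB's `iqr` convention and reproduces the published IQR rows exactly,
where R's default type 7 does not; the SD row likewise requires the
sample, not population, denominator. Percentages print at 2 decimals,
half away from zero (`round_half_up`).

## What the synthetic generator emulates — and what it does not

`generate_recording` draws an event schedule (integer-second onsets and
durations uniform on 10–25 s, minimum inter-event gap, uniform over
feasible placements) and synthesises one stationary band-limited Gaussian
process per band — white noise through the *same* brick-wall filters the
analysis uses, normalised to unit per-sample energy — mixed with
time-varying gains $\sqrt{w_b(t)}$. Outside events the default weights
are delta-dominant (0.70/0.15/0.08/0.04/0.03); inside events energy
shifts upward (0.25/0.15/0.15/0.20/0.25). These presets are fixture
choices that encode the qualitative low-to-high shift, not published
measurements. Both channels (`C3-A2`, `C4-A1`) share the band component
and add independent Gaussian noise (SD 0.3 relative to the unit-RMS
signal), so two-channel averaging measurably helps, and the whole record
is scaled to a typical 30 µV RMS for EDF export.

Two design points deserve emphasis:

* **Stationary synthesis, not per-segment energy normalisation.** An
  earlier draft rescaled each contiguous segment to its exact target band
  energies. That leaks class information through the *variance*: short
  apnea segments get tighter energy control than long non-apnea gaps, and
  the equal-weights null case classified at ~59 % instead of chance.
  With stationary per-band processes and gain switching, equal weights
  make apnea and non-apnea stretches literally the same process, and the
  measured null accuracy is ~51 % (binomial $p = 0.36$).
* **Energy fractions are exact globally, chi-square locally.** The
  whole-recording band fractions equal the weights up to filter leakage;
  a single 10 s frame fluctuates around them with ~10 % relative spread
  (about $2BT$ degrees of freedom per band). Tests therefore check the
  configured weights at the recording level and as a mean over frames,
  not per individual frame.

The generator does **not** emulate sleep microstructure (spindles,
K-complexes, stage transitions), artifacts, non-Gaussian amplitude
statistics, or EOG/EMG/ECG channels. A green end-to-end test therefore
establishes that the pipeline recovers a band-energy shift of the stated
size from noisy two-channel data — not that the classifier would reach
the published clinical accuracy on real polysomnography.

Event placement uses the exact sorted-uniform-slack construction (sorted
uniforms over the schedule slack plus cumulative durations and gaps).
This samples the same distribution as rejection-sampling independent
onsets conditioned on feasibility, but runs in $O(n)$ and cannot stall at
high event density.

## Degenerate inputs

Flat frames (zero amplitude after mean removal) raise in
`preprocess_frame`; single-class subjects are skipped with a warning in
`evaluate_cohort` and raise in `evaluate_subject`; annotation overlaps
are merged to their union; frames straddling an event boundary or inside
the guard zone are excluded, and `balance_frames` errors when the guard
leaves fewer non-apnea than apnea frames (the message suggests shrinking
it). EDF export requires an integer sampling rate and pads to whole
1 s records; round-trip error is bounded by half a 16-bit quantisation
step.

## Known limitations

* Real-data absolute performance is not reproducible here: the clinical
  recordings are not redistributable, so the published per-subject
  percentages are covered through their confusion matrices (bundled as
  plain text and recomputed through the metric code) rather than through
  signal processing.
* The EDF reader covers the plain 16-bit subset with one common sampling
  rate; EDF+ annotations and mixed-rate files are out of scope.
* Frames are anchored to the recording start; event-aligned framing would
  yield slightly more apnea frames per event but a different protocol.
* The balanced design makes accuracy the mean of sensitivity and
  specificity; on unbalanced data the reported accuracy would need
  prevalence correction.
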