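---
title: "Detecting motor imagery from short-term TFR entropy: models, parameters and design choices"
author: "tfemi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting motor imagery from short-term TFR entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfemi)
```

## The model

A sensorimotor-rhythm BCI needs a reliable detector of the *intentional
non-control* state: is the user imagining a movement right now, or
resting? The detector implemented here rests on a complexity argument.
A time–frequency representation (TFR), taken in absolute value and
normalized to unit sum, is a two-dimensional probability distribution
over time and frequency. A signal carrying a single component
concentrates that distribution and has low entropy; each additional
simultaneous component spreads it and raises the entropy. Motor imagery
adds transient low-frequency components (movement-related potentials
and accompanying delta-band activity) to the otherwise sparse 0.2–5 Hz
band, so the short-term entropy of the band-limited EEG rises during
imagery relative to baseline — a direction-unspecific but highly
detectable signature.

Two entropies are computed from each normalized window $p$:
the order-$\alpha$ Rényi entropy
$R_\alpha = \frac{1}{1-\alpha}\log_2 \sum p^\alpha$
and the Shannon entropy $I = -\sum p \log_2 p$ (with $0\log 0 = 0$).
$\alpha = 3$ is the conventional order for TFR analysis: odd integer
orders damp the oscillating cross-terms of quadratic representations.
Since Rényi entropy is nonincreasing in $\alpha$, $I \ge R_3$ always —
one of the property tests.

## The representations

Eight Cohen's-class TFRs are implemented from their defining sums:

* **Spectrogram** (`tfrsp`) — squared modulus of the short-time Fourier
  transform with a frequency-smoothing window $h$.
* **Gabor** (`tfrgabor`) — the spectrogram with a Gaussian analysis
  window; under the discretization used here the two coincide exactly
  for equal windows, which is asserted in the tests.
* **Pseudo Wigner–Ville** (`tfrpwv`) —
  $\sum_\tau h(\tau)\, x(t+\tau)\, x^*(t-\tau)\, e^{-2i\pi k\tau/N}$,
  the classical integer-lag discretization with its doubled frequency
  convention (bin $k$ maps to $k f_s / 2N$). The input is
  preconditioned with the analytic signal to suppress
  negative-frequency interference.
* **Smoothed pseudo Wigner–Ville** (`tfrspwv`) — adds a time-smoothing
  window $g$; $g = \delta$ reproduces the PWV bit for bit.
* **Reassigned variants** (`tfrrsp`, `tfrrgab`, `tfrrpwv`,
  `tfrrspwv`) — each cell's absolute mass is relocated to the grid
  cell nearest the local center of gravity of signal energy. Centroids
  use the classical ratio-of-auxiliary-transforms operators: the
  lag-weighted window $Th(\tau) = \tau h(\tau)$ for the time shift and
  the window derivative $Dh$ for the frequency shift; for the PWV,
  which involves no time smoothing, the time centroid is the cell's own
  time. Ties round toward the lower bin, off-grid mass clips to the
  boundary, and cells below $10^{-12}$ of the peak stay in place, so
  total absolute mass is conserved exactly — a tested invariant.
  Relocating *absolute* mass (rather than signed values) keeps
  reassigned surfaces nonnegative, which is what the probabilistic
  entropy reading requires.

Window defaults follow classical toolbox practice, since sharper
guidance rarely exists in applications: Hamming $h$ of the next odd
length at or above a quarter of the signal, Hamming $g$ at a tenth,
Gaussian ($\sigma = L/6$) for the Gabor pair, and 64 frequency bins
over $[0, f_s/2)$ — ample resolution for the 20 Hz feature signals.
Every fast implementation is checked against a literal brute-force
transcription of its defining sum at tolerance $10^{-10}$.

## The feature and decoding chain

Preprocessing mirrors standard MI practice: downsample to 200 Hz,
1–40 Hz fourth-order zero-phase Butterworth (applied forward–backward,
so the effective magnitude order is eight and the group delay zero),
epoch −5.5…2 s around the imagery onset, reject trials whose non-EOG
peak exceeds 100 µV (a conventional threshold, configurable), remove
ocular contamination, band-limit to 0.2–5 Hz, downsample to 20 Hz and
keep 31 motor-area channels. Two choices deserve comment:

* **EOG handling.** Component-based ocular cleaning (ICA plus manual
  component selection) is inherently operator-dependent. The package
  instead uses deterministic multichannel least-squares regression of
  every EEG channel on the EOG channels (with intercept), fitted on the
  trial-concatenated data. The residuals are exactly decorrelated from
  the EOG channels — a tested invariant — and the step is seedless and
  reproducible. The surface leaves room to plug in a component-based
  cleaner if one is available.
* **Order of band-limiting.** The 0.2–5 Hz amplitude filter is applied
  to the epochs, after artifact handling, matching the listed order of
  the standard chain. Note the composition with the earlier 1–40 Hz
  filter makes the effective amplitude-feature band 1–5 Hz; content
  below 1 Hz does not survive, which matters when interpreting slow
  potentials.

Entropy features slide a centered window (1 s or 0.5 s, 50 ms step —
one sample at 20 Hz, so centers sit on sample instants) along each
trial/channel TFR. Only centers where the full window fits produce
values; no padding is invented at epoch edges, and downstream decoding
restricts itself to valid centers. Each window is normalized to unit
sum *per window* (rather than per trial), which makes values comparable
across window lengths and keeps both entropies well defined in bits;
the switch is local to `short_term_entropy()`. An all-zero window
reports the maximum $\log_2(\text{cells})$ with a warning rather than
aborting a batch run.

Decoding fits an LDA per time point on the 31 channel values, with the
pooled within-class covariance shrunk toward the scaled identity by the
analytic Ledoit–Wolf intensity — the standard deterministic meaning of
"shrinkage LDA" in BCI work, robust when channels outnumber samples.
"Fivefold with 75/25 splits" is internally tense (five folds would
imply 80/20); it is realized as five repeated stratified random 75/25
splits at *trial* level, so a trial's MI and baseline samples never
straddle the train/test boundary. For MI-vs-baseline tasks each trial
contributes one MI sample and one baseline sample, with time points
paired by rank order inside their windows. Accuracy and F1 are averaged
over folds per time point, over the MI period per participant, then
grand averaged over participants with equal weight.

## What the synthetic generator emulates

`synth_config()` encodes the study conditions: 7.5 s trials
(−5.5…2 s around MI onset) with baseline (−3.5…−2 s), pre-MI (−2…0 s)
and MI (0…1.5 s) segments; classes "right"/"up"; conditions
VtG/noVtG (labels only — no physiological difference is generated, as
none is asserted for detection); 1 kHz, 31 motor channels + 3 EOG;
40 trials per class per participant, five participants.

Per trial the generator injects:

* pink (1/f) background noise, broadband RMS 2 µV — the residual noise
  level of a cleaned recording;
* mu (10 Hz) and beta (20 Hz) rhythms over the sensorimotor strip,
  attenuated by `erd_depth` (default 0.5) on contralateral channels
  during MI. This event-related desynchronization is the classical SMR
  signature, but note it lies *outside* the 0.2–5 Hz amplitude band and
  therefore cannot drive the low-frequency features — it is generated
  for realism and for validating the generator itself;
* an ongoing slow cortical rhythm (~1.2–1.8 Hz, 8 µV), the single
  dominant component of the analysis band at rest. Its presence is what
  gives the baseline a *low*-entropy, concentrated TFR against which
  added components are visible;
* a class-dependent biphasic movement-related potential (5 µV) during
  MI whose spatial pattern differs only slightly between classes —
  classes are nearly inseparable by design, as in real center-out MI;
* `complexity_boost` (default 4) transient tone/chirp components
  (1.2–4.8 Hz, ~10 µV, 0.8–1.5 s) during MI only, with random
  class-independent frequencies, onsets and spatial patterns. These are
  the mechanism of the entropy effect: more simultaneous components
  during MI than at baseline;
* stereotyped 300 ms biphasic blinks on the EOG channels, leaking into
  EEG with a frontal gradient (gain 0.2). Blinks are placed uniformly
  over the whole recording rather than segment-locked: tying them to
  one segment would build a spurious baseline/MI difference into the
  null configuration, which must stay exchangeable when all effects are
  switched off (a tested property).

Amplitudes sit in the physiological few-to-tens-of-µV range and were
fixed once as the package's default study conditions. With them, the
pipeline reproduces the method's qualitative signature: grand-average
MI-vs-baseline accuracy above 90% for short-window Shannon entropy of
the reassigned PWV, clearly above the amplitude-feature accuracy on
identical data, while direction decoding from entropy features stays at
chance. What the generator does *not* emulate: volume-conduction
forward modeling, non-stationary artifacts other than blinks,
inter-participant variability beyond independent random draws, or any
genuine vibrotactile-condition effect. Passing tests therefore
demonstrate correctness of the machinery and internal consistency of
the method's premise — not performance on real recordings, where the
size and stability of the complexity change is an empirical question.

## Numerical and degenerate-input choices

* Resampling applies a zero-phase 8th-order Butterworth anti-alias
  low-pass at 90% of the target Nyquist before spline interpolation
  onto the output grid; duration is preserved within one output sample
  and DC is passed exactly.
* Zero-phase filtering extends the signal by odd reflection at both
  ends before the forward-backward pass, so the long transients of
  low-cutoff high-pass stages settle outside the retained span.
* The zero-phase filter refuses signals shorter than six times the
  filter order plus padding; band edges must lie strictly inside
  $(0, f_s/2)$.
* Wigner–Ville outputs are real by construction (Hermitian lag kernel);
  the imaginary residue is tracked and must stay below $10^{-10}$
  relative.
* Entropy windows with no positive mass yield the maximum-entropy
  sentinel with a warning; unnormalized inputs to the entropy functions
  are an error, not silently rescaled.
* F1 with $TP = FP = FN = 0$ is undefined and reported as `NA` with a
  warning; fold averages skip it.
* The balanced-class empirical chance level is reported by permutation
  (`scripts/acceptance.R` prints it) rather than assumed.

## Problem sizes

The shipped study runs five participants × 80 trials × 31 channels at
1 kHz generation / 20 Hz features, with TFRs on 150-sample epochs and
64 frequency bins — about four minutes end to end on one core, with
each trial/channel TFR computed once and shared across entropy kinds
and window lengths. The oracle-equivalence tests run on signals of at
most 64 samples, where literal transcriptions of the defining sums are
affordable.

## Known limitations

* Only the amplitude-criterion (plus optional variance-outlier) trial
  rejection is implemented; GUI-based artifact inspection is out of
  scope.
* The EDF/BrainVision readers cover the common single-rate,
  int16/float32 cases; GDF is not parsed.
* Reassignment near signal edges inherits the usual boundary bias of
  finite-support windows; interior-region behavior is what the
  covariance and concentration tests assert.
* Multiclass decoding and non-linear classifiers are deliberately
  absent; the method is a binary detector.
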