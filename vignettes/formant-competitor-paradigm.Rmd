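---
title: "Building and scoring formant-competitor stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and scoring formant-competitor stimuli}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formantcomp)
```

## The paradigm

Speech carries much of its phonetic information in the frequency contours
of its lowest formants. When several voices overlap, a listener must
select and group the right subset of formants from the mixture. The
second-formant-competitor (F2C) paradigm probes this selection process:
three-formant synthetic analogues of sentences are presented dichotically
(left ear = F1 + F2C, right ear = F2 + F3), and the extraneous competitor
formant — derived from the target F2 but phonetically uninformative —
must be rejected for the sentence to be understood. Because F2C sits in
the opposite ear from the target F2, and below it in frequency next to
the more intense F1, its impact on intelligibility is informational
masking: interference beyond anything attributable to energetic overlap
in the auditory periphery.

This package implements the stimulus computation and the analysis layer
of that paradigm: contour manipulation, competitor construction, formant
synthesis, condition planning, intelligibility scoring, and psychometric
fitting. Human data collection, formant estimation from recordings, and
grapheme-to-phoneme conversion are out of scope; formant tracks and
phoneme sequences are inputs (or are generated synthetically).

## Contour model

A formant track is a frame-sampled pair of contours — frequency (Hz) and
linear amplitude — at 1-ms frames. All frequency manipulations act on a
log scale about the geometric mean of the whole frequency contour,

$$ g = \exp\!\big(\tfrac1N \sum_i \log f_i\big), $$

computed unweighted over all frames. The geometric mean is the right
pivot because formant excursions are approximately symmetric on a log
axis, and unlike the spectral centroid it is unaffected by amplitude
variation.

**Depth scaling** (the "formant squash") rescales deviations from the
pivot:

$$ \log s(t) = \log g + x \,\log\!\frac{f(t)}{g}, \qquad 0 \le x \le 1 .$$

$x = 1$ is the identity, $x = 0$ collapses the contour to a constant at
$g$, and intermediate values shrink excursions proportionally —
acoustically similar to constraining how far the articulators move from
their average positions. The operation preserves $g$ exactly (the scaled
log-deviations still average to a multiple of zero), which the property
suite asserts to relative error $10^{-9}$ over random tracks. Amplitude
contours are never rescaled anywhere in the package.

**Spectral inversion** reflects the contour about the pivot,
$s(t) = g^2/f(t)$: an involution that preserves both the rate and the
depth of frequency variation while destroying its phonetic content —
hence a speech-*like* competitor.

**Triangle-wave competitors** replace the contour with a regular,
arbitrary, not-speech-like pattern matched to F2's average rate and depth
of variation. The shape is the first four odd harmonics of the
triangle-wave Fourier series,

$$ a(t) = \frac{8}{\pi^2} \sum_{n \in \{1,3,5,7\}} \frac{1}{n^2}
   \cos\!\big(2\pi n (t + \varphi T)/T\big), $$

truncated so that peaks and troughs are slightly rounded (abrupt
resonator-frequency changes cause synthesis artifacts). The series is
normalized by its analytic peak $\frac{8}{\pi^2}(1 + \tfrac19 +
\tfrac1{25} + \tfrac1{49})$, attained at phase zero, so $\hat a(t)$ spans
exactly $[-1, 1]$ regardless of how frames sample the phase. The
frequency contour is then

$$ f(t) = g \, \exp\!\big(x\, r\, \hat a(t)\big), $$

where $r$ is half the log-range of the raw (unsmoothed) target F2 and
$x$ the depth scale factor. We deliberately use this multiplicative form:
a formulation that *adds* $\exp(x r \hat a)$ to $g$ would be
dimensionally incoherent and could not produce a contour that is
triangular on a log axis, centred on $g$, with peak-to-trough range equal
to F2's maximum-to-minimum range — which is the stated geometry of the
construction. With the multiplicative form the log-range is exactly
$2xr$ and the contour's geometric mean equals $g$ whenever the track
spans a whole number of half-cycle pairs; with an odd number of
half-cycles the deviation is phase-dependent and shrinks as the cycle
count grows.

**Period estimation.** The triangle period $T$ is matched to F2's
modulation rate in four steps: (a) block-average the F2 contour over 40
frames (equivalent to low-pass filtering a 1-ms-frame contour at 25 Hz),
which suppresses spurious crossings from small fluctuations near the
mean; (b) count crossings of $g$ as sign changes between successive
smoothed samples and take crossings + 1 as the number of half-cycles;
(c) halve to get cycles, keeping half-cycle precision; (d) divide the
track duration by the cycle count. A sample exactly at $g$ is treated as
positive — the tie must break one way, and this choice means a contour
that touches the mean without crossing it adds no half-cycle. A trailing
partial block is averaged over its own length rather than dropped, so no
part of the contour is ignored. The estimator is exact on noiseless
log-sinusoids of 1–20 full cycles at the default frame rate, which the
suite checks.

**Constraints.** Competitor amplitude contours are constant at the RMS
power of the target F2's amplitude contour. Every competitor must keep
its nominal frame frequency at least 80 Hz from F1 at every moment —
close approaches cause audible interactions between harmonics exciting
different formants. Separation is checked between nominal frame
frequencies only (no bandwidth or filter-skirt allowance), because the
constraint is stated on nominal frequencies. Triangle starting phases are
drawn uniformly on $[0, 1)$ of a period from a seeded generator and
redrawn (budget: 100) until the constraint holds; inverted and constant
competitors that violate it raise a structured error naming the worst
frame — this implementation reports violations rather than silently
excluding sentences, since an exclusion policy is an experiment-design
decision, not a stimulus computation.

## Synthesis

The excitation is a monotonous (F0 = 140 Hz) train of Rosenberg-style
glottal pulses: a cubic rise over the open phase (0.6 of the period) and
a quadratic fall over the closing phase (0.2), conventional values for
this source model. Cycle boundaries are placed by accumulating
instantaneous phase per sample, so the fractional period at 22.05 kHz
(157.5 samples at 140 Hz) is honoured on average — cycle lengths
alternate 157/158. By default the returned excitation is the first
difference of the flow (the glottal-flow derivative), folding in the
+6 dB/octave lip-radiation characteristic as is conventional in
source-filter synthesis; without it the steep source spectrum leaves the
fundamental dominating every formant.

Each formant is a two-pole resonator with pole radius
$\exp(-\pi B/f_s)$ and pole angle $2\pi F/f_s$ — the standard synthesizer
formulation — with gain normalized to unity at the instantaneous centre
frequency. Coefficients are recomputed every sample from the per-sample
linearly interpolated frequency contour. The 3-dB bandwidths are constant
at 50, 70 and 90 Hz for F1–F3; competitors use 70 Hz, matching the target
F2. Parallel outputs are weighted by the per-sample-interpolated
amplitude contours and summed with alternating polarity (+, −, +), which
avoids deep spectral zeros between adjacent formant peaks; uniform
polarity is available as an option. 10-ms raised-cosine onset and offset
ramps are applied per ear.

Absolute sound pressure level is not reproducible in software, so levels
are relative: a configurable digital reference (−25 dBFS long-term RMS by
default) stands for the experiment's 72-dB SPL reference, and each ear is
scaled to `reference + offset` dB. The dichotic conditions use +3 dB
(left) and −7 dB (right): the overall dichotic reference level is raised
3 dB to compensate for the loudness cost of splitting the formants
between the ears, and the right (F2+F3) ear sits about 10 dB below the
left (F1-dominated) ear, reflecting the natural intensity relation
between F1 and the higher formants. If the offsets would clip, assembly
raises an error unless joint auto-normalization is requested. Output is
16-bit PCM WAV at 22.05 kHz.

## Experiment designs

`build_condition_table()` encodes the three designs: 11 diotic conditions
scaling all target formants from 100% to 0% depth in 10% steps; 7
dichotic conditions with inverted competitors (control with F2 absent,
0–100% depth in 25% steps, dichotic reference without competitor); and 8
dichotic conditions with triangle competitors at 0–100% depth plus a
100% inverted comparison, an F2+F3-only control and the dichotic
reference. In the competitor experiments the target formants are always
scaled to 50% depth, while competitor depth is specified *relative to the
unscaled F2* — so `build_stimulus()` derives competitors from the raw F2
track, not the squashed one. Sentences are allocated to conditions in
equal consecutive blocks rotated cyclically across listeners, so a full
rotation cycle presents every sentence in every condition exactly once.
Per-competitor seeds are derived by hashing the corpus seed with the
sentence and condition ids, making any single stimulus reproducible from
the corpus seed alone.

## Scoring

Tight keyword scoring counts a keyword correct only if its exact
normalized form (case-folded, punctuation-stripped) appears among the
response tokens, with homonym alternatives accepted from an explicit map
and one-to-one token consumption so a single response word cannot satisfy
two keywords. No stemming is applied — tight scoring forbids it. Because
sentences carry 2–5 keywords, condition means pool over keywords
(`100·Σcorrect/Σkeywords`) rather than averaging per-sentence
percentages.

The phonemic score comes from a minimum-cost global alignment of the
response phoneme sequence against the reference, by dynamic programming
with costs substitution 10, insertion 7, deletion 7 — the convention of
the standard speech-recognition scoring tools, under which one
substitution (10) is preferred over a deletion-plus-insertion pair (14).
Ties are broken preferring substitution, then deletion. The score is
`100·hits/ref_len`; insertions do not reduce it. The alignment is
verified against exhaustive enumeration of all order-preserving matchings
for every string pair up to length 4 over a three-symbol alphabet, plus a
seeded sample of length-5/6 pairs (the full length-6 cross product is
about 1.2 million pairs; the enumeration size is capped to keep the suite
fast, the property being checked is identical).

Competitor efficacy expresses a condition's intelligibility loss relative
to two anchors: `100·(ref − cond)/(ref − control)`, where the dichotic
reference (no competitor) defines 0% and the control in which the
competitor replaces F2 defines 100%. It is undefined when the reference
does not exceed the control, and is invariant to common positive affine
rescalings of all three scores.

## Psychometric fitting

Intelligibility versus scale factor is summarized by the Weibull
psychometric function
$\Psi(x) = \gamma + (1 - \gamma - \lambda)\big(1 - e^{-(x/\alpha)^\beta}\big)$
with guess rate $\gamma$, lapse rate $\lambda$, inflection $\alpha$ (in
scale-factor percent) and slope $\beta$. The loss is unweighted least
squares on mean proportions — matching a curve fit to condition means —
with optional binomial weighting when per-point trial counts are
supplied. Fitting uses bounded Levenberg-Marquardt
(`minpack.lm::nlsLM`) with box constraints
$\gamma, \lambda \in [0, 0.5]$, $\alpha \in (0, 2\max x]$,
$\beta \in [0.1, 10]$, started from a fixed grid of 20 $(\alpha, \beta)$
combinations to escape local minima; the best-converged fit wins.
Noiseless data are recovered to $10^{-4}$; under binomial noise at 11
points × 260 trials, the median recovery error across 100 seeded
replicates is within ±10% for $\alpha$ and ±25% for $\beta$ (both
asserted by the suite).

## The synthetic corpus generator

`make_tracks()` emulates the *inputs* the paradigm needs, not speech
itself. Each formant's log-frequency contour is its centre log frequency
(defaults 500, 1500, 2500 Hz — the nominal formants of a standard adult
male vocal tract) plus a sum of 3–5 random-phase cosines with rates drawn
from 2–6 Hz, the band typical of articulator movement; the deviation is
rescaled so the half log-range equals the spec's excursion exactly
(defaults 0.18, 0.22, 0.12 for F1–F3). Band-limited cosine sums were
chosen over filtered noise precisely because their log-ranges and cycle
counts are analytically known, so they double as test oracles. Durations
are drawn uniformly from 1.5–2.5 s, the range of short test sentences.
Amplitude contours are raised-cosine syllabic envelopes at 4 Hz with a
small floor, scaled 1 : 0.4 : 0.15 across F1–F3 so F1 dominates as in
natural speech spectra. The generator validates $F_1 < F_2 < F_3$ and
$F_2 - F_1 \ge 200$ Hz at every frame and fails loudly if the requested
bands make that impossible.

What the generator does *not* emulate: formant-tracker estimation errors
(the occasional rapid anomalies that real inverted competitors inherit
from low-amplitude frames), consonantal occlusions with near-zero energy,
covariation between formants, or natural pitch contours. Passing tests
therefore demonstrate the correctness of the stimulus computation and the
analysis chain under clean, controlled contours — not robustness to
tracker artifacts. One consequence of the clean geometry is that the
synthetic F2 band sits far above F1, so the 80-Hz separation constraint
is satisfied with a wide margin (minima of several hundred Hz); the
constraint machinery (violation detection, phase redraw) is exercised
separately with adversarial geometries in the unit tests.

Simulated listeners report each keyword correctly with independent
probability $\Psi(x)$ of the condition covariate; no lexical confusion
structure is modelled, because none is specified by the paradigm.

## Numerical choices and degenerate inputs

* Geometric means are unweighted over all frames, including low-amplitude
  frames; excluding occlusion frames would require an amplitude threshold
  the paradigm does not define.
* Inversion and depth scaling commute (shared pivot), so the order —
  inversion first, then scaling — is unobservable and tested as such.
* A track whose amplitudes are all zero flattens to all-zero with a
  warning (it synthesizes to silence) rather than an error.
* An all-constant contour never crosses its mean: one half-cycle,
  $T = 2 \times$ duration.
* WAV samples are clipped to $[-1, 1]$ and quantized to 16 bits; a
  write-read round trip agrees within one least significant bit.
* Frame-to-sample conversion linearly interpolates between 1-ms frame
  values with constant extrapolation at the edges.

## Problem sizes used by the test suite

The suite runs the property checks at sizes chosen to finish in a few
minutes on one core while leaving no property unexercised: 1000 random
tracks for the contour-algebra invariants, a 50-sentence corpus for the
corpus-wide separation audit, a 16-sentence corpus through the full
synthesis pipeline, 100 replicates for noisy Weibull recovery, and the
alignment enumeration sizes given above.

## Known limitations

* The original analogue synthesizer's exact resonator-gain and
  amplitude-control semantics are unknown; unity gain at the
  instantaneous centre frequency is a modelling choice, as is the
  alternating summation polarity.
* Only voiced (buzz-excited) excitation is implemented; unvoiced
  frication and natural pitch contours are out of scope.
* The homonym set and exact alignment penalties used by any particular
  laboratory differ; both are configurable inputs here.
* Exact reproduction of published psychometric parameter values is not
  attempted: those derive from human listeners and a proprietary recorded
  corpus, while this package reproduces the computation applied to such
  data.
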