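---
title: "QRS delineation by polygonal approximation: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QRS delineation by polygonal approximation: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqrs)
```

## The problem

An ECG beat consists of a P wave, the QRS complex and a T wave; the
clinically important landmarks (fiducial points) are the onsets, peaks
and offsets of these deflections. Peaks are easy: they are amplitude
extrema with a large rate of change. The QRS onset and offset are not —
they sit at the boundary between the waveform region and the baseline,
where the amplitude changes slowly and every sample looks like its
neighbours. Threshold rules on the raw samples are therefore fragile,
and the difficulty is compounded by morphological variety: the Q or S
deflection may be absent, the whole complex may point downward, and
ventricular ectopic beats widen and notch it.

`polyqrs` addresses both problems structurally rather than by tuning
thresholds:

* a **polygonal approximation** reduces each R-R section to a small
  ordered vertex set. Because the onset/offset is the corner between
  baseline and waveform, it survives as a vertex across a wide range of
  approximation tolerances, and at vertex resolution its feature values
  stand out sharply from the few competing vertices;
* a **cumulative amplitude-change signal** over those vertices
  normalizes away polarity and Q/S-presence variation before any
  feature is measured.

## Pipeline

### Preprocessing

An order-2 Butterworth band-pass of 1–25 Hz suppresses baseline wander
(respiratory drift, roughly 0.15–0.3 Hz) and powerline interference
(50/60 Hz). The filter is applied forward and backward (zero phase,
effective order 4): any group delay would bias the very timings the
package measures. Edge transients are controlled by odd-reflective
padding of five time constants of the slow edge (`5 * fs / low_hz`
samples). Band edges and order are configurable (`bp_low`, `bp_high`,
`bp_order`); `filter = FALSE` skips the stage for pre-filtered input.

### R-peak detection and segmentation

The classic Pan-Tompkins chain runs on a detection-only signal
(5–15 Hz band-pass, five-point derivative, squaring, 150 ms centered
moving-window integral, dual adaptive thresholds with search-back and a
200 ms refractory period). Two refinements matter for this package:

* over a symmetric QRS the integrated signal can plateau, leaving the
  raw detection at the plateau edge; detections are first snapped to the
  squared-derivative maximum (the steepest QRS limb) nearby;
* the returned index is the extremum of the *absolute* 1–25 Hz-filtered
  amplitude within ±50 ms (inside the normal QRS half-width, given a
  normal QRS width of about 0.08–0.12 s), which makes the index
  polarity-robust and places it on the signal actually used for
  delineation.

The detector is pluggable: externally supplied R annotations (e.g. from
a database) bypass it. Delineation always operates on R-R sections
between consecutive refined peaks, endpoints shared.

### Polygonal approximation

All geometric quantities are computed on **axis-normalized
coordinates**: within each segment, time is rescaled to [0, 1] over the
R-R interval and amplitude to [0, 1] over the segment's range. Angles
and distances on sampled physical units are meaningless without such a
convention; normalizing per segment makes `support_k`,
`curv_threshold` and `tolerance` dimensionless and transferable across
sampling rates and gains, and makes vertex *positions* exactly
invariant under polarity flips and uniform amplitude scaling (the
package asserts this invariance in its tests).

1. **Initial vertices** — the k-cosine curvature at sample `i` is `pi`
   minus the interior angle formed by the chords to samples `i − k` and
   `i + k` (computed with `atan2`, which stays well-conditioned where
   `acos` loses precision near collinearity). Strict local maxima above
   `curv_threshold`, plus the segment endpoints (the R-peaks, trivially
   high-curvature poles), form the initial set.
2. **Sequential refinement** — between each initial-vertex pair, a
   vertex is inserted at the sample of maximum perpendicular deviation
   from the covering chord, recursively, until every deviation is at
   most `tolerance`. The recursion tree does not depend on the
   tolerance, so the vertex set shrinks monotonically as the tolerance
   grows.
3. **Dynamic-programming repositioning** — within each initial-vertex
   interval the added vertices are moved (endpoints fixed, strict
   ordering, count unchanged) to minimize the total squared *vertical*
   error of the piecewise-linear reconstruction. Vertical rather than
   perpendicular error is used because it admits an exact O(n²)
   chord-cost precomputation via prefix sums; the DP is then exact, and
   the tests verify equality with exhaustive enumeration. Equal-cost
   placements resolve deterministically (leftmost choice at each
   backtracking step).

Defaults: `support_k = round(0.02 * fs)` (20 ms, sharper than the
narrowest QRS feature), `curv_threshold = 0.15` rad, `tolerance = 0.02`
(2% of the segment amplitude range). Vertex positions are stable across
tolerance choices precisely because fiducial corners are high-contrast;
this stability is what licenses scoring only vertices.

### Cumulative signal

Vertex amplitude differences `vyD_i = vy_i − vy_{i−1}` (first element 0)
are rectified and summed: `vyD'_i = sum_{k<=i} |vyD_k|`. The result is
non-decreasing, starts at 0, ends at the total variation of the vertex
amplitudes, and is *identical* for a beat and its polarity-flipped twin.
A beat with or without Q/S deflections, upright or downward, maps to a
cumulative signal of the same monotone shape with a steep central rise —
that is what makes one scoring rule work across morphologies. The
cumulative signal is kept at vertex resolution; no downstream feature
ever looks at raw samples again.

### Vertex scoring

For each segment, onset candidates are the interior vertices within
`window_s` (default 0.3 s) *before* the segment-ending R-peak, offset
candidates those within `window_s` *after* the segment-starting one.
0.3 s bounds any plausible QRS boundary (normal width 0.08–0.12 s, wide
ventricular complexes included) while excluding most of the P wave.
Each candidate receives four weights, all in [0, 1] on the search set:

* `ω_A` — cumulative-amplitude distance from the far R-peak, normalized
  by the maximum over the search window. Near the fiducial this is
  close to maximal; at a mid-QRS notch it is small, because most of the
  beat's amplitude change still lies between the notch and the boundary.
* `ω_T` — time distance from the reference point 0.3 s away from the
  R-peak, normalized by `0.3 * fs`. Larger is better: this suppresses
  P-wave vertices, which are far from the R-peak.
* `ω_C(θ) = (cos θ)^0.5` on the baseline-side chord angle: the square
  root keeps the weight high even when noise or drift tilts the
  baseline chord by 30–40°.
* `ω_S(θ) = (sin θ)^2` on the waveform-side chord angle: the square
  sharply suppresses vertices whose waveform-side chord is not steep.

The onset maximizes `ω_A(A^R) + ω_T(T^R) + ω_C(θ^L) + ω_S(θ^R)`; the
offset mirrors it with left/right roles swapped. Ties break toward the
R-peak (the conservative, shorter-QRS reading). An empty search set is
reported as a detection failure for that beat, never an error for the
record; the first beat of a record has no onset-side segment and the
last no offset-side, and both are emitted with `complete = FALSE`.

### Angle axis scaling

Chord angles need an aspect ratio. The x-reference is the search window
(`window_s * fs` samples). For the y-reference, the total cumulative
range is too coarse: a shallow Q deflection (say 0.12 mV against a
2.7 mV total variation) then maps to ~30°, where `(sin θ)^2` fails to
reward the true onset's waveform-side chord and the *Q-trough* vertex —
steep on both sides — outscores it. The y-reference is therefore a
fraction `angle_y_frac = 0.1` of the total cumulative range: a
deflection of 10% of the beat's amplitude change spread over the whole
0.3 s window maps to 45°, so genuine QRS limbs (including small Q/S
waves) map near 90° while baseline chords stay near 0°. The fraction is
configurable; it was chosen from the geometry above, and the package's
recovery tests document its adequacy across the morphology classes.

### Exponent choice

The rendered form of the scoring rule elsewhere reads `cos θ` for the
baseline weight, while its accompanying rationale describes adding a
square root; the package defaults to `(cos θ)^0.5` and `(sin θ)^2` and
exposes both exponents (`cos_exponent`, `sin_exponent`), so the
literal-cosine variant is one flag away.

## The synthetic generator

Beats are sums of five Gaussian deflections. Defaults (center offset
from the R peak in seconds, width σ in seconds, amplitude in mV):

| wave | center | σ | amplitude |
|------|--------|------|-----------|
| P | −0.220 | 0.025 | 0.15 |
| Q | −0.028 | 0.008 | −0.12 |
| R | 0.000 | 0.010 | 1.00 |
| S | +0.028 | 0.008 | −0.20 |
| T | +0.300 | 0.050 | 0.35 |

These give a 104 ms QRS at 250 Hz, inside the normal 0.08–0.12 s band,
with physiological amplitude ratios. Morphology classes are reached by
parameter choice: `include_q`/`include_s` drop deflections, `polarity`
inverts the beat, `widened` scales the QRS centers and widths (the
PVC-like class uses factor 2, a larger S, and no P wave), and an
optional extra Gaussian injects a notch. The notch default sits on the
*terminal limb* of the widened complex (center 0.036 s, σ 0.005 s),
because a small bump injected into the steep R–S downslope is simply
absorbed by the slope and never produces a distinct vertex — a
modelling observation, not a detector property.

Ground truth is analytic: the true onset is 3σ before the center of the
earliest included QRS component and the true offset 3σ after the latest
(99.7% of the deflection lies inside, matching the visual
baseline/waveform boundary). Wave centers are snapped to the sample
grid, so truth indices are exact integers, and noise is added after
truth is fixed — noise never moves ground truth. A Gaussian-sum model
was preferred to a dynamical-system simulator precisely because the
truth is closed-form; the price is realism. The generator does **not**
emulate heart-rate variability, respiration-modulated amplitudes,
electrode-motion spikes, or genuinely non-stationary noise, so passing
recovery tests demonstrate correctness of the algorithm under its
stated model, not field performance on ambulatory recordings.

Noise follows the standard taxonomy: a baseline-wander sinusoid
(default 0.25 Hz, inside the 0.15–0.3 Hz respiratory band), a powerline
sinusoid (50/60 Hz), and white Gaussian noise, all seeded and
bit-reproducible.

## Evaluation protocol

Each reference fiducial is paired with the nearest detection of the
same label within a 150 ms window (larger than any plausible
delineation error, smaller than half the shortest R-R interval); the
signed error is `(detected − reference) · 1000 / fs` ms, negative =
early. Per-record means and sample SDs (n − 1 denominator) are averaged
*unweighted* into the aggregate μ and σ, so long records do not
dominate. Stability is judged against the CSE inter-expert tolerances —
σ ≤ 6.5 ms (onset) and ≤ 11.6 ms (offset), boundary inclusive. When two
channels are delineated against a single annotation stream, the channel
with the smaller `|mean| + sd` is selected per record (a per-beat
selection would be an alternative reading; per-record is implemented
and flagged in the report). QR (onset→R) and RS (R→offset) section
lengths, grouped by beat label, provide a reference-free consistency
statistic for databases that annotate only beat types.

## Numerical and interface choices

* In-memory sample indices are 1-based (R convention); all on-disk
  formats (CSV, WFDB) store 0-based indices, converted at the I/O
  boundary. Error statistics use index differences and are unaffected.
* Curvature uses `atan2(|cross|, dot)` rather than `acos` of the cosine
  for precision near collinearity; boundary samples without full chord
  support get curvature 0.
* A segment with zero amplitude range normalizes to a constant; its
  curvature is 0 everywhere and its approximation is the two endpoints.
* `ω_A` degenerates when the search window has zero cumulative range
  (flat segment); it is then defined as 0 for all candidates.
* Deterministic tie-breaks throughout: leftmost DP placement, ties
  toward the R-peak in scoring, channel 1 on equal channel criteria.
* The WFDB reader supports signal formats 212 and 16 with gain/baseline
  conversion to physical units, and the standard binary annotation
  format with SKIP escapes; code 1 maps to `Rpeak`, `'('` to `Qon`,
  `')'` to `Soff`, other codes to their mnemonics. Which annotator file
  of a multi-annotator database is "the" reference is a harness
  configuration choice.

## Problem sizes used by the test suite

The recovery tests run at 250 Hz with 0.8 s R-R intervals: 52-beat
records per morphology class for clean and noisy parameter recovery, a
102-beat record for the vertex-preservation check, 60-beat records per
polarity for the R-peak detector, 57 notched wide beats for the
notch-robustness check, and 200–500 randomized cases for the DP,
deviation-bound and cumulative-identity properties. These sizes give
stable proportions while keeping the default suite under a minute.

## Known limitations

* P-wave and T-wave delineation are out of scope; only the QRS
  onset/offset (and R peak) are produced.
* Very short R-R intervals (< 0.6 s) make the onset and offset search
  windows overlap; the windows are then still anchored to their own
  R-peaks, but a T wave squeezed against the next QRS can enter the
  onset window.
* The evaluation harness accepts local WFDB files but the package ships
  no database; headline per-database error tables require the user to
  supply recordings and annotations.
* Beat-type classification is not performed; section statistics group
  by externally supplied labels.
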