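---
title: "Quantifying duct contractility from time-lapse stacks: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying duct contractility from time-lapse stacks: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ductokym)
```

## The measurement problem

A duct segment imaged under transmitted light shows two dark wall bands on a
bright background. Spontaneous smooth-muscle activity narrows the wall-to-wall
distance for a few seconds at a time, at rates of roughly 1.5–15 beats per
minute. The quantity of interest is almost always a *frequency*: events per
two-minute window, compared before and after a drug addition. Secondary
quantities are the axial propagation of contractions (peristalsis) and the
motion of luminal contents (pendular vs net transport).

All geometry is kept in pixel units unless the user supplies a pixel size;
frequencies are in beats/min and are pixel-scale free. Time of frame *i*
(0-based) is `i * frame_interval_s`; every window in the package is half-open
`[a, b)`, so abutting windows partition events exactly.

## Kymograph extraction

A kymograph is the stack resliced along a fixed line: `K(s, t)`, position
along the line × frame. Intensity is sampled by bilinear interpolation at a
spacing as close to 1 px as divides the line length evenly, so both
endpoints are sampled and reversing the line flips rows. The interpolation
uses the difference form `f11 + fx (f12 - f11) + fy (f21 - f11) + fx fy
(...)`, which is exact on constant images and linear in intensity; both
properties are tested. `width_px > 1` averages that many unit-spaced
parallel lines. A sample that falls outside the image after width offsetting
is an error, never clamped: clamping would silently bias wall positions. The
section width of the original visual procedure is unknown; the default is
1 px and user-settable.

## Diameter tracing

Per time column, the two deepest local minima of the intensity profile
(plateau-aware, separated by at least 3 px) are taken as the walls, each
refined by a parabola through its neighbours, giving sub-pixel diameters.
Because only intensity *ordering* enters, the trace is invariant under
monotone affine intensity maps (tested). Columns without two separable
minima become gaps; more than 25 % gaps rejects the line as untrackable.

The baseline is a 60 s centered running median — at least five times longer
than any physiological pulse, so it tracks slow drift without following
pulses. At the trace ends the first/last full-window value is held
(`endrule = "constant"`): the shrinking-window alternative lets the baseline
collapse onto a contraction that happens in the first frames and mask it.
Residual noise is `1.4826 * MAD` of the detrended trace.

## Event detection and frequency

Contractions are diameter *decreases*; detection runs on minima of the
trace. Wall displacement would work too, but diameter is invariant to rigid
motion of the whole duct, which makes it the more robust equivalent of
reading spikes off the kymograph by eye. Steps, in order:

1. smooth with a centered 3-frame mean (shrunk to 2 frames at the ends, so
   an event in the very first frames survives);
2. find plateau-aware local minima; take the raw-trace minimum within each
   plateau (earliest on exact ties);
3. prominence = baseline − trough; keep events with prominence at least
   `max(3 * noise_sd, 0.03 * median baseline)`. The relative floor (3 % of
   the diameter) guards against counting noise wiggles on clean traces; the
   3-sigma term takes over on noisy ones. The original counting was visual,
   so both constants are package choices, exposed as arguments and flags;
4. enforce a minimum spacing of 3 s, keeping the deeper event of any
   conflicting pair and the earlier one on exact ties. 3 s sits just below
   the 4 s period of the fastest physiological rate (15 beats/min);
5. refine each event time by a parabola through the trough. Sub-frame times
   cost nothing at 1 frame/s and make latency fits across stations
   resolvable at 7 frames/s.

Events are never reported inside gap stretches. A trace shorter than twice
the minimum interval is an error. Frequency is `60 * count / window` over a
half-open window; an empty window is 0 beats/min, not an error — a segment
with no spontaneous events is a quality-control failure, which the pipeline
flags and excludes from statistics rather than analyses.

## Peristalsis and luminal flow

Wave speed comes from event latencies across three or more stations. Events
are matched by rank (k-th with k-th) after dropping stations whose event
count deviates from the modal count — nearest-in-time matching was rejected
as harder to reason about and to test. Event time is regressed on station,
pooled over events with per-event centering; speed is the reciprocal slope,
signed along increasing column. A fitted lag across the span below half a
frame interval is not resolvable and classifies as `global`; a coherent fit
(`r^2 >= 0.8`) as `propagating`; anything else as `incoherent`. When the
lag is under one frame interval the result recommends capture at 7 frames/s.

Flow uses the longitudinal centerline kymograph. Consecutive profiles are
z-scored (hence offset and scale invariance) and aligned by maximum circular
cross-correlation over ±15 px with parabolic sub-pixel refinement; circular
lags match the simulator's wrapped particles and cost nothing on real
profiles where the search range is small. The cumulative displacement is
fitted with a robust line (M-estimate); `net_transport` needs `|net| >
max(0.5 px/s, 2 SE)`, otherwise `pendular` needs a residual oscillation
amplitude (`sd * sqrt(2)`, exact for a sinusoid) of at least 1 px, otherwise
`static`. The source observations are qualitative here, so all three
thresholds are package choices validated only against the simulator. A
featureless lumen (contrast within noise) is a warning plus `static`, not an
error.

## Paired drug-epoch statistics

The epoch design measures frequency in `[t-120, t)` and `[t+10, t+130)`
around each addition at `t`; the 120 s window and 10 s delay are the
established design constants. The spontaneous baseline ("Spont") is the
pre-window of the *first* addition only; later pre-windows are reported but
not tested. Windows leaving the recording, or a post-window overlapping the
next addition's pre-window, are errors naming the addition.

The Friedman statistic is computed from within-row ranks (mid-ranks on
ties):

\[ Q = \frac{\tfrac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}{C}, \qquad
   C = 1 - \frac{\sum (t^3 - t)}{n (k^3 - k)} \]

with p from the chi-square approximation on `k - 1` df, retained even at
small `n` to match common practice. The tie correction is the classical one,
algebraically identical to `stats::friedman.test` (which serves as an
independent cross-check in the tests, never as the implementation); when
every row is fully tied, `C = 0` and the convention `Q = 0, p = 1` applies.
An exact permutation p — full enumeration of within-row rank permutations,
merged by rank-sum state so `6^n` products stay tractable — is available
with `exact = TRUE`. At `n = 5, k = 3` the chi-square approximation can
differ from the exact tail by more than 0.1 in the middle of the
distribution, so the exact option is the one validated against a brute-force
oracle in the tests.

Dunn's post hoc uses `z = (\bar R_i - \bar R_j) / \sqrt{k(k+1)/(6n)}`,
two-sided normal p, adjusted over the comparisons actually performed.
Bonferroni is the default — the multiplicity family of the original
software is not stated, so exact reproduction of its adjusted p-values is
not claimed — with Holm available. Default comparisons are every condition
against "Spont". Stars mark adjusted p < 0.05 and < 0.01.

## The simulator

`simulate_movie()` renders the analytic model the analysis chain is
validated against: intensity `background − wall_depth [G(r; top) + G(r;
bot)] − particles + noise`, walls at `center ∓ D(c, t)/2`, and

\[ D(c, t) = D_0 \left(1 - A\, p(t - \tau(c))\right), \qquad
   \tau(c) = (c - c_0)/v \]

with `p` a raised-cosine unit pulse repeating at the active regime's
interval (a smooth waveform; the true waveform is unknown, only that spikes
are brief) and `τ` the peristaltic lag (zero for `"global"`). Regime changes
(drug schedules) switch the interval at the first onset at or after the
change time, so no pulse is truncated. Particles advect as `x(t) = x_0 + u t
+ a \sin(2\pi t / P)`, prescribed rather than pressure-coupled — coupling
flow to wall motion is out of scope. Output is clipped to [0, 1] and
quantized to 16-bit levels so a written TIFF round-trips bit for bit; one
seeded generator drives noise and particle placement, so a parameter set
plus seed reproduces a movie exactly.

Defaults are chosen once as plausible for a transilluminated duct at around
100× magnification: 64 × 192 px frames, resting diameter 30 px, wall sigma
2 px, background 0.85, wall depth 0.5, particle depth 0.35, intensity noise
SD 0.01, contraction amplitude 20 % (amplitude is never reported in the
source setting beyond "largely constant", so this is the implementer's
choice, kept moderate), pulse width 3 s. The pulse width is capped at half
the contraction interval: at 15 beats/min a fixed 3 s pulse would keep the
duct contracted three quarters of the time — a tonic pattern, precisely what
the tissue does not do — and any baseline-plus-prominence detector
(including this package's) degenerates on a signal that rests less than half
the time. The cap leaves every preset and documented example untouched
(8 s interval → 3 s pulse).

What the simulator does *not* emulate: tissue texture and collagen optics,
curvature and 3-D geometry, photobleaching, focus drift, amplitude
variability, and mechanochemical coupling of flow to contractions. Passing
the validation therefore shows the chain is correct on an idealized duct
with known truth; it does not certify performance on adverse real
recordings, where line placement and thresholds may need the exposed
overrides.

## Validation problem sizes

The acceptance-style tests run the chain at the scale the questions demand:
the reference preset (240 s, 1 frame/s) for the worked 7.5 beats/min example
and position invariance; 120 movies (six frequencies spanning 1.5–15
beats/min × 20 seeds, amplitudes 0.1–0.2, noise up to 0.02) for frequency
recovery within ±0.5 beats/min in ≥ 95 % of runs; 100 amplitude-zero movies
for the false-positive control; 7 frames/s peristaltic movies for 10 %
wave-speed recovery; the two flow presets for classification; and 200 random
5 × 3 tables against brute-force rank-sum and permutation oracles for the
statistics. Unit tests use smaller movies (typically 48 × 64 px, 20–120 s)
of the same model.

## Known limitations

* Wall tracking assumes exactly two dominant dark bands per transverse line;
  crossing ducts or strong luminal debris on the line can steal a minimum
  (such columns become gaps, and > 25 % gaps reject the line).
* Rank matching for wave estimation needs a common event count across
  stations; heavily missed detections at one station exclude it rather than
  re-align it.
* The flow estimator reports bulk profile displacement; it cannot separate
  multiple particle populations moving differently.
* The chi-square Friedman p is anti-conservative at very small `n`; use
  `exact = TRUE` for final inference on few segments.
* Analysis lines are straight; strongly curved ducts need several short
  transverse lines rather than a curved reslice.
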