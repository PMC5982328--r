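---
title: "Footwear-aware gait identification: model, generator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footwear-aware gait identification: model, generator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitid)
```

## The identification model

A walking subject is represented by per-stride stance recordings of the
three ground-reaction-force components per limb — anterior–posterior
`Fx`, vertical `Fy`, lateral `Fz` — plus a body height measured by two
depth sensors. Identification is open-set: the answer is an enrolled
subject or `NONE`.

**Phase model.** The stance occupies about 60 % of the gait cycle and is
split into loading response (0–10 % of the cycle), mid stance (10–30 %),
terminal stance (30–50 %) and pre-swing (50–60 %). Because the force
plate records the stance only, these become the stance fractions
[0, 1/6), [1/6, 1/2), [1/2, 5/6), [5/6, 1]. `segment_stance()` places
boundaries at `round(fraction * n)` with half-away-from-zero rounding,
0-based half-open windows that tile the samples exactly. Whether the
original experiments used per-subject measured stance/cycle ratios
rather than the nominal 60 % is unknowable from the outside; the nominal
value is adopted because the generator and the segmenter then share one
constant and segmentation stays deterministic per stride length.

**Distances.** Two series are compared by classic dynamic time warping:
local cost `|a_i − b_j|`, symmetric unit-weight steps (1,0), (0,1),
(1,1), endpoints anchored, no band by default (an optional Sakoe–Chiba
band is exposed for long series). DTW is used as a dissimilarity — it is
nonnegative, symmetric and zero on identical series, but no triangle
inequality is claimed. A phase distance sums the three per-component DTW
costs over one limb's phase window; the whole-stride distance sums all
six component/limb alignments. Forces are normalised to fraction of body
weight before alignment so heavier subjects do not dominate the cost;
path-length normalisation is *not* applied — the distances are plain
accumulated sums, matching their additive composition. This yields five
distances per probe/gallery-stride pair,
`ρ_MSt,L, ρ_TSt,L, ρ_MSt,R, ρ_TSt,R, ρ_Stride`; together with the
measured body height they form the six-element fusion vector
(`distance_vector()`). Loading response and pre-swing carry low forces
whose within-subject variability exceeds between-subject variability,
so no voter operates on them.

**Footwear stage.** The loading-response window of `Fx` and `Fy` of both
limbs is fit by a least-squares polynomial of degree 5, time rescaled to
[0, 1] (so coefficients are comparable across stride durations), force
in fraction of BW. Coefficients are ordered by descending degree in
blocks (x, L), (x, R), (y, L), (y, R): 24 features. The default
classifier is a radial-kernel soft-margin SVM on standardised inputs
(`e1071::svm`, cost 1); the kernel and cost are configurable and a
distance-weighted kNN is available for comparison. The original
hyperparameters behind the reported footwear accuracy are not published;
the defaults here are documented, not claimed to match. Validation uses
subject-grouped 10-fold cross-validation: folds partition people, never
strides, so identity never leaks across folds. Heels is the positive
class for sensitivity/specificity.

**Height stage.** Per frame, body height is the sum of the trunk chain
(head → neck → spine shoulder → spine mid → spine base) plus the mean of
the two leg chains (hip → knee → ankle → foot) plus a fixed head-top
offset (12 cm by default, covering head-joint-to-vertex and
foot-joint-to-ground; generator and estimator share the constant so the
noise-free round trip is exact). A segment requires both endpoint joints
`fully_tracked`; a failed leg segment falls back to the contralateral
segment, averaged over whichever sensors supply it, and a frame that
still cannot be resolved is skipped and counted. The published
description fixes the exact fallback order only loosely and shows the
joint chain only graphically; the chain above is a documented
reconstruction. The walk-level height is the mean over usable frames,
which averages out the within-cycle oscillation and the sensor noise.
When the footwear stage reports heels, 5 cm (the rounded mean
heel-height effect) is subtracted; the gate then retains enrolled
subjects within ±2 cm of the corrected height, boundary inclusive
(subjects differing by *more than* 2 cm are excluded). Enrolled heights
are sport-shoe measurements, since the gallery is built from sport-shoe
sessions in the footwear-change scenarios.

**Decision stage.** Each of the five distances drives a kNN voter over
the reduced gallery (k = 5 by default; `min(k, gallery size)` when the
gate leaves fewer strides). The neighbour at rank R contributes
`w_R = (k + 1 − R)/k`; each voter therefore distributes exactly
`(k+1)/2` weight. The published voting formula indexes weights by rank
but sums over classifiers, leaving open whether a class occupying
several ranks within one voter scores once or repeatedly; the
accumulate-all-ranks reading is adopted (every neighbour contributes its
rank weight) because the decision variable is defined per *neighbour*.
Ties on distance break by enrollment order (stable sort); the label with
the largest total wins; `NONE` is returned when two classes tie on the
total, when the winning total is below `Th` (default 0, the most liberal
strategy), or when the reduced gallery is empty.

## The synthetic-data generator

The generator stands in for an unreleased cohort of 99 women (own sport
shoes and 8–10 cm heels, 14–20 cycles per footwear). It emulates exactly
the statistical structure the pipeline relies on, with all randomness
derived from one root seed through fixed substreams
(`population → subject → stride/walk`), so identical configurations are
bit-reproducible.

*GRF morphology.* Each component is a shape-preserving piecewise-cubic
(PCHIP with Fritsch–Carlson slopes, written in the package because the
stock `monoH.FC` interpolant overshoots at interior extremum nodes)
through control points given as (fraction of stance, fraction of BW):

| component | control points | reading |
|---|---|---|
| Fy | (0, 0), (0.25, 1.20), (0.50, 0.80), (0.75, 1.20), (1, 0) | overload and propulsion maxima ≈ 120 % BW, sub-BW unloading minimum |
| Fx | (0, 0), (0.22, −0.20), (0.50, 0), (0.78, 0.20), (1, 0) | braking minimum just before the first Fy maximum, propulsion maximum just after the second, mid-stance zero crossing |
| Fz | (0, 0), (0.20, ±0.10), (0.50, ±0.10), (0.80, ±0.10), (1, 0) | lateral plateau ≈ 10 % BW, positive left / negative right |

With zero slopes at extremum nodes the curve extremes *are* the control
amplitudes, so calibration targets are honored by construction up to the
sampled perturbations. Identity lives in between-subject perturbations
of the control points (multiplicative amplitude SD 0.05, timing SD
0.012 of stance); stride-to-stride repeatability in the smaller
within-subject perturbations (0.012 / 0.004). The paper-side cohort's
true within/between variance ratio is not published, so this
separability knob is a free parameter: defaults were chosen once so that
the same-footwear closed-set scenario lands in the high-90s CCR region
reported for real data, and the evaluation asserts scenario *orderings*,
never absolute rates.

*Footwear effect.* Heels scale extreme amplitudes by 1.10, shorten the
stance by factor 0.95, and shift the weight-acceptance extremes of `Fx`
and `Fy` 3 % of stance earlier (`heels_time_shift = -0.03`). The first
two follow the reported qualitative directions (higher GRF extremes,
shorter stride). The timing shift is this package's own addition: a pure
amplitude scaling of 10 % is of the same order as the between-subject
amplitude variation, which makes footwear classes inseparable for
held-out subjects — unlike the ~96 % footwear accuracy observed on real
data — whereas an earlier, more abrupt weight acceptance is both a
recognised consequence of the reduced heel rocker and a shape cue that
restores realistic separability. All three knobs are configurable.

*Anthropometry.* Body weight ~ N(607.2, 108.6) N and sport-shoe height
~ N(166.41, 5.74) cm match the reported cohort; the heel-height effect
on measured height is N(4.988, 0.7504) cm (positives enforced by
redraw). Walking height oscillates sinusoidally at stride frequency with
a per-subject peak-to-trough amplitude ~ |N(4, 0.8)| cm capped at
9.5 cm, the largest excursion reported for normal walking. Skeleton
frames at 30 fps place all chain joints on a vertical line with segment
lengths in fixed proportions of the instantaneous height, so the
estimator's chain sum is exact on fully tracked frames; per-sensor
height noise (SD 1 cm — "a few centimetres" of per-frame error) and
independent per-joint dropout to `inferred` (probability 0.05) emulate
measurement degradation. Both legs are generated symmetric, which makes
the contralateral fallback exact.

*What the generator does not model* — and what passing tests therefore
do not show about real data: left/right asymmetry, per-subject stance
timing idiosyncrasies beyond Gaussian jitter, double support overlap
between limbs (both limbs' stances are generated aligned), experience
effects of heel wearers, foot-placement-dependent `Fz` changes, sensor
cross-talk or synchronisation error, and any musculoskeletal dynamics.
Absolute scenario rates are meaningful only relative to each other.

## Numerical and implementation choices

- DTW runs in C++ with a single rolling row; cost grows as the product
  of series lengths. The brute-force warping-path enumeration used as
  the test oracle is exponential and only run on series of length ≤ 6.
- Stance windows: `round(fraction · n)` half-away-from-zero; a stance
  needs ≥ 12 samples (two per sub-phase), a loading-response fit ≥ 6.
- The degree-5 fit solves the Vandermonde system by QR
  (`qr.solve`); the tests cross-check against a normal-equations solve.
- Ensemble totals compare with an absolute tolerance of 1e-12 when
  detecting ties.
- Degenerate inputs: an empty reduced gallery yields `NONE`, not an
  error; unresolvable skeleton frames are skipped and counted; an
  all-frames-unresolvable log errors.
- Generator draws that must be positive (weights, heights, heel deltas,
  cycle durations) are redrawn rather than truncated at zero.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run entirely on synthetic data
sized for a desk machine: calibration batches of 200 strides (20
subjects), a 10,000-subject population for the heel-delta distribution,
and a scenario grid of 50 subjects × 10 repetitions with 4 strides per
subject per footwear at a simulation sampling rate of 120 Hz (the
960 Hz default of the stride format is used for calibration targets;
DTW distances are rate-consistent within a run, so the identification
orderings do not depend on this choice). Rates in reports are rounded
to 2 decimals, and CCR + FRR + FAR = 100 holds per report cell up to
that rounding.

## Known limitations

- The ±2 cm gate presumes the enrolled and probe heel heights match the
  5 cm correction; lower heels would be over-corrected and can gate the
  true subject out — the open-set `NONE` path absorbs such cases but
  accuracy drops.
- The footwear stage is binary; a third footwear class or a regression
  of the height correction would require retraining, not redesign.
- `FAR` follows the closed-cohort convention (wrong-subject assignments
  among enrolled probes); impostor probes are scored separately via the
  `enrolled` flag of `identification_metrics()`.
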