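---
title: "Decoding stimulus transitions from population rates: models and methods"
author: "popdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus transitions from population rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdecode)
```

This vignette is the package's account of its science: the decoding
model, the information estimator, the minimal encoding model, the
synthetic data generator, and the numerical and design choices behind
each.  All quantitative statements here are computed by the package's
test suite or by the code shown; none are asserted from memory.

## The question and the experimental design

After an abrupt image transition, the firing of visual-cortical neurons
reflects a mixture of the waning response to the previous image and the
rising response to the current one.  The package asks what *single*
image that mixture encodes at each moment, by decoding the instantaneous
population rate vector against a measured dictionary of per-pattern
population responses.

The stimulus set is deliberately tiny: a 2×2 tile "miniature image",
each tile black (0.01 Cd/m²), gray (6 Cd/m²) or white (60 Cd/m²), tiled
periodically across the screen, giving P = 3⁴ = 81 patterns
(`enumerate_patterns()`).  Because the stimulus is periodic, all
computations operate on the 2×2 miniature image; tile-level receptive
fields are sufficient statistics for the synthetic units.  Pattern ids
are the base-3 encoding of the tile levels (UL, UR, LL, LR; black = 0,
gray = 1, white = 2), a stable ordering that keeps dictionaries
comparable across runs.

Two presentation paradigms are scheduled by `build_schedule()`, each 250
ms per period, each repetition a fresh random permutation of all 81
patterns: the *dictionary* paradigm inserts a 250 ms gray blank before
every pattern (isolated responses → the population code) and the *relay*
paradigm shows patterns back-to-back (the transitions to be decoded).
Ten interleaved repetitions give 810 relay transitions and 20
permutations in total.

One bookkeeping convention is ours: each relay repetition is prefixed
with a single 250 ms gray adaptation period, so the first pattern of a
repetition has a well-defined gray predecessor (its normalized contrast
is the zero vector and contributes 0 to previous-pattern averages).
Every one of the 810 pattern periods then counts as exactly one
transition.

## The correlation-weighted dictionary decoder

The dictionary `RR` (`build_dictionary()`) holds mean firing rates,
patterns × sites, averaged over a window after pattern onset (0–90,
90–250 or 0–250 ms) and over repetitions.  The normalization at the
heart of the method maps any vector v to
(v − mean v)/‖v − mean v‖, so that the dot product of two normalized
vectors *is* their Pearson correlation.  The formula's denominator is
the Euclidean norm of the centered vector, not the standard deviation;
the two differ only by a factor √(n−1) that cancels in correlations,
and the norm form makes `R %*% r` literally a vector of correlations
computed "by multiplication and summation".  A constant vector (no
spatial contrast, e.g. the all-gray pattern, or a flat population
vector) maps to the zero vector, and every correlation with it is 0 by
convention — this single convention handles all degenerate inputs in
the decoder, with no special cases downstream.

Decoding one population vector (`decode_instant()`) computes
`c = R r` (one correlation per pattern) and the correlation-weighted
image `d = normalize(Σ_p c_p S_p)`, where `S` holds the normalized
contrast codes (black 1, gray 0, white −1).  The maximum-correlation
pattern id is also reported (the argmax variant), but the weighted
average uses the information in all P correlations rather than only the
winner.  `correlation_timecourse()` applies this per 10 ms bin to every
relay period and correlates `d` with the normalized previous pattern,
current pattern and difference pattern (element-wise contrast
subtraction B − A before normalization, values in {−2,…,2}); means and
standard errors (sd/√n) are taken across transitions.

`crossover_time()` reports when the current pattern overtakes the
difference pattern.  Two choices are ours.  First, a persistence rule:
the crossing must hold for k consecutive bins (default 3 × 10 ms) to
suppress single-bin noise.  Second, the crossing is searched only after
the difference-dominated epoch has begun (the first bin with
difference > current): in the first bins after a transition the decoded
image is still the previous image, so the current-pattern correlation
trivially exceeds the (then negative) difference-pattern correlation,
and without this guard every trace would "cross" at t = 0.

`window_split_consistency()` decodes the same relay data with a 0–90 ms
dictionary and a 90–250 ms dictionary and correlates the two
difference-minus-current time courses: a high correlation means the
population code is the same before and after the crossover — the
transmitted message changes, not the code.

The site-inclusion criterion (`significance_mask()`) follows the
convention that a site responds significantly if its mean evoked rate
strictly exceeds baseline mean + 2 sd.  We operationalize the baseline
on the trial-averaged PSTH: the mean rate per bin position over the
last 100 ms of all pre-pattern blanks, with mean and sd across those
bin positions.  (Taking instead each 100 ms window as one sample makes
the criterion's 2 sd ≈ 20 spk/s for Poisson counts at typical rates,
which no realistic evoked response clears; the PSTH reading is the one
under which the criterion does useful work.)  Decoding itself uses all
sites by default — the mask matters for the information analysis.

## Mutual information with shuffle bias correction

Per site and 10 ms bin, counts across all presentations are discretized
into four equal-width intervals spanning [min, max + 1): for the range
0–7 this gives 0–1, 2–3, 4–5, 6–7 spikes.  For ranges not divisible by
four we keep continuous interval edges and assign by floor — this
reproduces the canonical 0–7 example exactly and generalizes without
ad-hoc rounding.  A degenerate range (all counts equal) is defined to
carry 0 bits.  The empirical joint P(r, s) then gives
I = Σ P(r,s) log₂ P(r,s)/(P(r)P(s)), with 0·log 0 = 0.

The raw estimate is biased upward by limited sampling (10 repetitions
per pattern), so the mean information over random stimulus-label
permutations is subtracted; corrected values can be slightly negative
by construction.  The number of shuffles (default 20) is a
configuration choice balancing the variance of the bias estimate
against run time.  Note that the correction is *degenerate when every
label is unique* (one repetition per pattern): permuting distinct
labels only permutes joint-table columns and the corrected information
is identically zero — the tests therefore always use repeated labels,
as the design prescribes.  Information about the previous stimulus
pairs each label with the counts observed one full period (250 ms)
later; periods without a contiguous successor (repetition boundaries)
are dropped.  Trace averages include only sites passing the
significance mask.

## The minimal encoding model

The minimal model (`encode_pixel()`, `unit_drive()`) says: a unit's
membrane potential is the pixel luminance contrast convolved with a
temporal response function trp[t]; for OFF regions the kernel is
inverted; the encoded image is ON minus OFF.  For a step from image A
to image B the linearity of convolution gives, at lag t,

eis(t) = B·cum(t) + A·tail(t),

where cum(t) is the kernel's cumulative sum and tail(t) the kernel mass
at lags beyond t (within one 250 ms period, tail = integral − cum).
With a biphasic kernel of small net integral, tail ≈ −cum over the
early transient and eis ∝ B − A: the model encodes the *difference
image*.  Late in the period, once the kernel support is exhausted,
eis ∝ B times the net integral: a weak sustained representation of the
current image.  A kernel with exactly zero integral would encode only
the difference image forever — the positive net integral is what buys
the late current-image epoch.

The kernel itself is configuration, parameterized as a difference of
two gamma lobes (`trp_kernel()`): positive lobe peaking at 40 ms
(shape 5), undershoot peaking at 60 ms (shape 4), undershoot/positive
area ratio 0.9, sampled at 1 ms over 250 ms, scaled to unit peak.  The
timing is in the range of cortical impulse responses estimated by
reverse correlation, and the ratio puts the model's
difference-to-current crossover near 130 ms with a clear
difference-dominated epoch — the qualitative regime the analysis is
about.  All four numbers are exposed; nothing downstream assumes them.

`reverse_correlate()` closes the loop: it estimates the kernel from
white-noise stimulation (default 8.3 ms frames) as the
spike-count-weighted spike-triggered average per pixel, averaged over
driving pixels with OFF pixels sign-flipped, optionally scaled to unit
peak.  The test suite verifies recovery (r ≥ 0.9 against the generating
kernel at 10⁵ frames) under rectified-linear Poisson spiking.

## The synthetic population generator

`make_population()` + `simulate_responses()` stand in for a 16-site
laminar probe.  Each unit has a signed weight 4-vector over tiles
(positive = ON sub-region, negative = OFF), the shared kernel, a gain,
a baseline rate and a 25 ms latency;
rate(t) = baseline + gain·max(0, drive(t − latency)) and counts are
Poisson per bin (default 10 ms; 1–50 ms supported).  The rectified
linear mapping is the simplest one consistent with treating membrane
potential and firing rate as monotonically related; no further
nonlinearity is modeled.  Units are drawn as sign-opposite pairs
(w, −w), mirroring ON- and OFF-dominated multiunits, so the population
carries both contrast polarities through the rectification — this is
what lets a linear decoder read a rectified population.

Drives are scaled so that a unit-contrast step reaches peak drive 1;
gain is therefore "evoked spikes/s per unit contrast at the transient
peak".  Defaults (gain 80–200 spk/s, baseline 2–8 spk/s, uniform) are
multiunit-scale: evoked responses a few-fold above baseline, peak 10 ms
bin counts in the single digits — the regime in which the 4-interval
count discretization of the information estimator is exercised (0–7-ish
ranges), and in which a majority of sites clear the significance
criterion.  The noiseless mode returns the Poisson means themselves, a
real-valued tensor used by the oracle tests (e.g. the dictionary equals
the generator's windowed rates exactly; self-decoding is perfect).

What the generator does *not* emulate: correlated variability across
sites (counts are conditionally independent Poisson), laminar or areal
structure, complex-cell (phase-invariant) responses, spatiotemporal
inseparability (no velocity representation), adaptation beyond the
kernel's undershoot, and eye movements.  Passing tests therefore show
that the analysis chain is correct and that the phenomenology follows
from a biphasic kernel plus rectified Poisson units — not that real
cortex satisfies these assumptions.

## The orientation test

The orientation analysis asks whether single units, not just the
population readout, signal the difference image.  A stationary square
grating (5/35 Cd/m², background 20 Cd/m²) follows either a gray blank
or a checker pattern (0, 10, 10, 60 Cd/m²) whose tile luminances are
arranged so that the average luminance *along* the grating orientation
does not change at the transition; all the luminance change is
orthogonal.  `orientation_test_stimuli()` describes the 16-orientation
set (22.5° steps) and the analytic difference-image orientation
(grating + 90°).

`fit_preference()` estimates preferred orientation as half the circular
mean angle of rate-weighted doubled orientations.  On a uniform grid
covering the full circle this equals the phase of a least-squares
cosine fit with period 180° — whether or not the fit carries a DC term,
since a constant has no doubled-angle component on a uniform grid — but
it is deterministic and needs no optimizer or tolerance.  It is
invariant to gain and additive offsets; an unmodulated tuning curve is
flagged undefined (NA) rather than given an arbitrary angle, and the
180° boundary wraps to 0.  `preference_shift()` wraps differences to
[0, 90]°.

`model_orientation_shift()` simulates the test on a pixel grid (48×48
px, 8 px tiles, Gabor receptive field with 10 px envelope SD) using the
step-response algebra above, averaging rectified drive in the 25–90 ms
window.  One geometric choice deserves its own paragraph: the checker's
spatial phase *along* the stripes.  The full-screen tiled stimulus
fixes the checker-to-grating alignment across stripes (that is the
luminance-invariance construction) but leaves the along-stripe phase
free relative to any particular receptive field — real units sample it
at random.  The canonical model unit uses the phase for which the
difference image is in phase with its receptive field; the opposite
phase puts the difference response on the unit's sign-opposite partner
instead (the rectified unit itself would simply fall silent at the
orthogonal orientation, and the preference shift would be carried by
other units of the population).  With this geometry the noiseless model
shifts its preference by 90.0° (the acceptance script recomputes this),
and a 17-unit population with random preferred orientations and Poisson
noise scatters around that value.

## Problem sizes, run times, and reproducibility

The default study conditions — 81 patterns, 10 repetitions per paradigm,
16 units, 10 ms bins, 20 information shuffles, 17 orientation-test
units — run end-to-end (`run_pipeline()`) in well under a minute on one
core; the test suite simulates one such session and reuses it across
tests.  Every stochastic stage takes a seed, and `run_pipeline()`
derives all stage seeds from the single config seed, so a run is
reproducible from its configuration alone; `write_counts()` /
`load_counts()` round-trip tensors losslessly through plain TSV.

## Known limitations

* The decoder assumes a monotonic rate–luminance relation per site
  (simple-cell-like coding); populations dominated by complex cells
  would violate it, as discussed above for the generator.
* The shuffle-corrected information estimator is the plain empirical
  histogram estimator; with very few repetitions its variance is large
  and the correction, though centered, does not remove it.
* A label-shuffle control of the decoder retains O(1/√P) accidental
  structure per permutation (a fixed permutation is shared by all
  transitions); null distributions should average several permutations,
  as the test suite does.
* The minimal model is temporal only: no spatiotemporal interaction, no
  direction selectivity, no nonlinear subunits.
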