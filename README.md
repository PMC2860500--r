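# popdecode

What image does a visual-cortical population encode right after the image
changes?  Not the new image, it turns out, and not the old one either: for
the first ~100 ms the population firing best matches the *difference*
between the current and the previous image, and only later the current
image itself.  `popdecode` implements the complete analysis chain behind
that question for multiunit spike-count data, together with a synthetic
population generator so the whole pipeline runs without recordings.

The package is aimed at systems neuroscientists working with population
rate decoding: it is equally usable on real spike-count tensors (loaded
from a plain long-format table) and on its own simulated data.

## The method

**Stimuli.** 2×2-tile luminance patterns (each tile black 0.01, gray 6 or
white 60 Cd/m², hence P = 3⁴ = 81 patterns) are shown for 250 ms each, in
two paradigms: a *dictionary* paradigm with a 250 ms gray blank before
every pattern (used to measure each pattern's isolated population
response) and a *relay* paradigm with patterns shown back-to-back (the
transitions to be decoded).

**Decoder.** Mean rates per pattern and recording site form the P×N
dictionary matrix `RR`.  Each row, and each instantaneous population
vector `rr`, is normalized as

    r = (rr − mean(rr)) / ‖rr − mean(rr)‖,

so dot products are Pearson correlations.  The correlation vector
`c = R r` weights the normalized stimulus patterns `S` (contrast code:
black 1, gray 0, white −1) to give the decoded image

    d_l = Σ_p c_p S_pl,   d normalized again.

Per 10 ms bin, `d` is correlated with the previous pattern A, the current
pattern B and the difference pattern B−A (element-wise contrast
subtraction, then normalization); averaging across all transitions gives
the correlation time course and its crossover time.

**Information.** Per site and time bin, spike counts are discretized into
four equal-width intervals spanning their observed range (0–1, 2–3, 4–5,
6–7 for a 0–7 range), the empirical joint distribution with the stimulus
gives `I = Σ P(r,s) log₂ P(r,s)/(P(r)P(s))`, and the mean information
under random stimulus-label permutations is subtracted (shuffle bias
correction).  Pairing labels with the counts one period later gives the
information about the *previous* stimulus.

**Minimal model.** A unit's membrane potential is the pixel luminance
contrast convolved with a biphasic temporal response function (ON minus
OFF regions); rates are rectified-linear with Poisson spiking.  The same
model explains the orientation-preference test: a grating preceded by a
suitable checker pattern produces a difference image orthogonal to the
grating, and the fitted preference (cosine phase over 16 orientations,
25–90 ms window) shifts by 90°.

## Worked example

```r
library(popdecode)

k <- trp_kernel()                     # biphasic temporal response function
mt <- model_correlation_timecourse(k) # all 81 x 81 transitions, model only
crossover_time(mt)
#> [1] 130
model_orientation_shift(k)
#> Orientation-preference shift: 90.0 deg (n = 1 unit; 90 deg = preference
#> follows the difference pattern)

report <- run_pipeline(default_config(seed = 1), quiet = TRUE)
report
#> Stimulus-transition decoding run (seed 1)
#>   transitions decoded: 810; significant sites: 16/16
#>   early window (50-90 ms) mean corr: prev -0.301, cur 0.577, diff 0.654
#>   late window (150-250 ms) mean corr: prev -0.090, cur 0.528, diff 0.444
#>   crossover (current > difference): 160 ms
#>   window-split consistency r = 1.000
#>   information peak (current): 0.088 bits at 70 ms
#>   model orientation shift: 89.2 deg
```

Reading the report: in the early window the decoded image correlates
*better with the difference pattern (0.654) than with the current pattern
(0.577)* and anti-correlates with the previous pattern; after the 160 ms
crossover the current pattern wins (0.528 vs 0.444).  Decoding with a
dictionary built from the 0–90 ms code or the 90–250 ms code gives the
same time course (consistency r = 1.00): the message changes, not the
code.  The information about the current stimulus peaks at 70 ms — while
the decoded image is still the difference image.  Across 17 noisy model
units the orientation preference shifts by ~90° when a grating follows
the checker pattern.

`plot(report$trace)`, `plot(report$info)` and `plot(k)` draw the
correlation time course, the information time course and the kernel.

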