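---
title: "Methods: simulating and analysing retinotopic working-memory fMRI"
author: "retinowm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing retinotopic working-memory fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Spatial relations come in two flavours: *categorical* relations are
abstract and region-based ("the dot is in the opposite quadrant"),
*coordinate* relations are metric ("the dot is at the same distance from
the centre").  If the two are processed by genuinely different
mechanisms, the attentional rehearsal that keeps a location in working
memory should distribute differently across the visual field under the
two instructions — and because early visual cortex is retinotopically
organised, that distribution is measurable: delay-period BOLD activity
in the parts of V1/V2/V3 that represent the region where a match would
occur can be compared against the parts that represent everything else.

`retinowm` implements that measurement chain end to end and, because no
raw data from such experiments are available to ship, pairs it with a
generative model of everything upstream: retinotopically organised
voxels, phase-encoded mapping runs, and two-stimulus working-memory
sessions with injectable, known delay-period effects.  Every analysis
stage can therefore be validated against ground truth, and the group
statistics can be calibrated against their nominal error rates.

# The simulated experiment

## Voxel sheets

`generateVoxelSheet()` draws `nPerArea` voxels for each of V1, V2 and V3.
A voxel is a point receptive field with a polar angle (0° at the upper
vertical meridian, increasing clockwise; quadrant Q1 is 0–90°, the upper
right) and an eccentricity in degrees of visual angle.  Voxels tile the
16 cells of the quadrant × eccentricity-ring grid, where the four rings
are centred on the task's four stimulus radii (1.875°, 3.75°, 5.625°,
7.5°; the two printed variants 1.9/3.8/5.6 are treated as rounded
duplicates of these analysis values).  Polar angles keep a 6° margin
from the quadrant borders and eccentricities stay inside their ring's
decoding boundaries, so ground-truth labels are recoverable by a
noiseless phase map — misassignment under noise is then a property of
the noise, not of the generator.  Cortical folding, voxel correlations
and area-specific receptive-field sizes are *not* modelled; the sheet is
the minimal structure the analysis contract needs.

## Mapping runs

A mapping run follows the standard phase-encoded design: eight 54,000 ms
cycles sampled every 540 ms, with 27,000 ms fixation-only blanks at both
ends (900 volumes per run; the protocol object also accepts other
geometries).  The wedge rotates clockwise; the ring expands from 0.4° to
7.5° with a width of 1/5 of the maximum radius.  Each voxel's neural
drive switches on when the stimulus reaches its receptive field — the
wedge's leading edge crossing its polar angle, the ring's centre
crossing its eccentricity — and stays on for the protocol's per-cycle
activation duration (7,200 ms).  Using the same on-duration as the
analysis regressor, rather than the exact wedge-overlap time
(45/360 × 54,000 = 6,750 ms), is a deliberate choice: the printed
activation window and the wedge width are mutually inconsistent for a
point receptive field, and adopting the regressor's window makes
noiseless phase recovery exact at every lag, which is the oracle the
test suite builds on.

## The cross-dot task

A session holds 80 trials — 40 match, 30 non-match, 10 catch — over 40
dot positions (10 per quadrant: 2 angles on each of the two inner rings,
3 on each of the two outer rings, evenly spaced strictly inside the
quadrant).  Each position appears exactly twice as the first stimulus;
the second stimulus is drawn at random among the positions that satisfy
(match) or violate (non-match) the active rule — diagonally opposite
quadrant under the categorical instruction, same radius under the
coordinate instruction.  A trial runs fixation (1,000 ms), S1 (300 ms),
a retention interval jittered uniformly on a 1,000 ms grid over
3,000–8,000 ms, S2 (300 ms), a 2,000 ms response window, then a
10,000 ms inter-trial interval; the stated 80-trial composition is
treated as authoritative over the (arithmetically inconsistent)
"each position twice as S2" description, so S2 usage is balanced only
as far as the composition allows.  Task sessions are sampled at 1,500 ms
per volume.

## BOLD signal and noise

Neural drives are sampled onto the volume grid — boxcars mark volumes
whose midpoint falls inside the on-window (this makes the cyclic
regressor activate exactly round(7,200/540) = 13 volumes per cycle at
every lag), impulses land in the volume during which they occur — and
convolved with a double-gamma HRF (response gamma shape 6, undershoot
shape 16, ratio 1/6, peak-normalised; convolution is exact, not FFT).
S1 and S2 add transient responses in the stimulated quadrant × ring
cell, optionally scaled by mean-centred stimulus eccentricity
(`eccAmp`) to emulate cortical magnification; during every retention
interval `delayMatchAmp` is added to the voxels of the instruction's
matching region and `delayMismatchAmp` to the mismatching region.
Catch trials contribute S1 and a delay truncated at the modeled S2 time
of a median-jitter (5,500 ms) trial, and no S2.  Noise is white
Gaussian per voxel (marginal SD `noise_sd`) passed through an AR(1)
recursion (`ar1Rho`, default 0.3), plus a shared linear + half-cosine
drift.  The defaults — unit noise SD, stimulus amplitudes 1.5, mapping
amplitude 3 — put mapping-run peak correlations around 0.6–0.8 and
first-level delay-beta standard errors around 0.03–0.05 signal units,
a mid-range SNR for event-related BOLD expressed in percent-signal-like
units.  What the generator deliberately omits: spatial noise
correlations, motion, physiological noise, behavioural-neural coupling
(accuracy and RT are drawn independently of the delay signal).  Passing
tests therefore certify the *analysis logic and its calibration*, not
robustness to every artefact of real data.

# The analysis chain

## Phase-encoded retinotopy

The cyclic regressor encodes 7,200 ms of activation per 54,000 ms cycle,
zero during the blanks, HRF-convolved.  For every voxel
`crosscorrMap()` computes the Pearson correlation with this regressor
at all 100 lags (one per cycle volume) after DCT high-pass filtering,
and the peak lag is the voxel's phase; ties break to the smallest lag,
constant series are flagged invalid.  Because the regressor already
carries the HRF, peak lag maps directly to stimulus position:
`lagToPolar()` is linear at 3.6°/lag from the configured start angle;
`lagToEccentricity()` maps lags linearly in radius from the ring's
starting centre eccentricity (inner limit + half a ring width = 1.15°)
to the maximum radius.  The correlation window includes the blank
lead/trail volumes (the regressor is zero there before convolution).

p-values use the correlation t-transform with N − 2 degrees of freedom,
uncorrected for the max-over-lags selection.  The Bonferroni mask
therefore defaults to a voxels × lags family: the union bound makes it
genuinely conservative despite the selection, whereas a voxels-only
family would be anti-conservative by roughly the effective number of
independent lags.  `significanceMask(nTests = <n voxels>)` restores the
voxels-only convention when wanted.

## Segment ROIs

Decoded polar angles are interpolated to four steps — the quadrants
0–90°, 90–180°, 180–270°, 270–360°, half-open bins with 360° wrapping
to the first — and decoded eccentricities to four rings with boundaries
at the midpoints between adjacent stimulus radii (midpoints join the
lower ring; values beyond the extremes clamp to rings 1 and 4).  Only
voxels surviving the significance mask are assigned.  Per trial, the
matching region is the diagonally opposite quadrant (categorical) or
the S1 ring across all quadrants (coordinate); the categorical
mismatching region excludes S1's own quadrant by default so that
residual S1 activation — modelled by the S1 factor — is not read as
delay-period mismatch activity (a switch includes it for sensitivity
analyses).  Under the coordinate instruction the matching ring
necessarily coincides with S1's ring, so delay-match and S1 activity
share a segment and are separated only temporally (event versus boxcar);
this identifiability limit is inherent to the design and shows up as a
somewhat less precise coordinate delay-match estimate.

## The concatenated-segment GLM

For one area, the four segment mean time courses are concatenated
(4 T volumes) and fitted jointly.  Five neural factors are placed in
the segment blocks where the corresponding activation is expected and
HRF-convolved strictly within their block (no spill across
concatenation seams): delay-match and delay-mismatch boxcars spanning
S1 offset → S2 onset, S1 and S2 impulse events in the block of the
stimulated segment, and an eccentricity modulator (the pooled S1+S2
events weighted by mean-centred stimulus radius; a single modulator is
used rather than separate S1/S2 modulators).  Each block receives its
own constant and eight DCT high-pass columns, so baselines never couple
across blocks.  Estimation is ordinary least squares — no prewhitening,
matching the modelling tradition this design comes from; the group
level inherits no bias from residual autocorrelation because inference
is across subjects.  On noiseless matched simulations all five betas
are recovered to machine precision, which the tests assert at 1e-6
relative tolerance.

Two design variants reuse the same machinery: the stimulus analysis
splits S2 events by whether the second stimulus fell in the trial's
matching region, and the reliability analysis models the stimulus
events of each segment group in *all four* blocks (16 columns), giving
per-group "contrast activation" — response in the segment containing
the stimulus minus the mean response where it is not — whose equality
across instruction × segmentation-mode conditions indicates equally
discriminative quadrant and ring maps.

## Group statistics

Delay betas (subject × area × instruction × region) enter a fully
within-subject three-way repeated-measures ANOVA, computed from
orthonormal within-subject contrast scores.  Both the univariate
sphericity-assumed F (with Greenhouse–Geisser correction) and the
multivariate Hotelling F with (q, n − q) degrees of freedom are
reported, because published analyses of this design are ambiguous about
which family produced their degrees of freedom; for
single-degree-of-freedom effects the two coincide.  The implementation
is validated in the test suite against `stats::aov` (univariate) and
`car::Anova` (multivariate), which reproduce its statistics exactly.
Follow-ups run the 2 × 2 instruction × region ANOVA per area with
paired match-vs-mismatch contrasts (uncorrected, as is conventional for
these post hocs, with Holm-adjusted values alongside).  Behavioural
accuracy and mean RT are compared by paired t-tests, with t defined as
0 for degenerate all-equal differences.  The contrast-activation values
enter both a one-way ANOVA over the four conditions and the 2 × 2
decomposition.

# Calibration and power machinery

`sessionTemplate()` freezes one session per instruction (trials,
regions, designs, QR decompositions) so that replicate first-level fits
reduce to applying a stored decomposition to fresh data;
`simulateCohortDelayBetas()` and `simulateCohortContrasts()` then
generate whole cohorts through the *actual* designs and estimator.
With zero injected amplitudes this is the matched-null generator: at
1,000 cohorts of n = 10 the three-way interaction and the reliability
ANOVA reject at 5% within Monte-Carlo error, which both the test suite
and `scripts/acceptance.R` recompute.  The injected-effect defaults
were fixed a priori from the standardised effect they imply: a
categorical match–mismatch difference of 0.3 signal units confined to
V3, with 0.1 between-subject SD and first-level standard errors near
0.04, is a within-subject effect of d ≈ 2 — a robust attentional
modulation — for which the per-area follow-up at n = 10 has high power,
while V1 (no injected effect) stays at its nominal false-positive rate.
The full-pipeline patterning run uses 20 cohorts of 10 subjects at 64
voxels per area; the calibration runs use 1,000 beta-level cohorts; the
phase-recovery checks use a 480-voxel sheet.  These sizes are the
package's standard demonstration scale and keep a complete validation
run in the minutes range on one core.

# Numerical conventions and degenerate inputs

* Volume-grid sampling: boxcar "on" iff the volume midpoint is inside
  the window; impulses go to the volume containing the onset.  This
  replaces a floor/ceil rule, which would have made the cyclic
  regressor 14 volumes wide and lag-dependent in edge cases.
* Convolution is direct sparse accumulation — exact zeros outside
  support, no FFT round-off.
* Tie-breaking: equal peak correlations resolve to the smallest lag;
  segment boundaries are half-open (polar) / lower-inclusive at
  midpoints (eccentricity).
* Rank-deficient designs abort with the collinear columns named;
  empty segments abort naming the segment; all-zero design columns
  (empty event lists, degenerate sessions) are dropped with a
  message/warning; constant voxels are flagged invalid and excluded.
* The effective high-pass cutoff is 8 cosines over the run length
  (≈ 8/(2 · 900 · 0.54) ≈ 8 × 10⁻³ Hz for a mapping run); a literal
  sub-hertz *high*-pass on BOLD data would remove everything, so the
  cosine count, not a printed cutoff frequency, is the configured
  quantity.

# Known limitations

Hemispheres are not modelled (lateralisation questions are out of
scope); eye movements and fixation quality are not simulated; the
behavioural generator shares no latent state with the neural generator;
OLS standard errors at the first level ignore AR(1) colouring (group
inference does not rely on them); and the coordinate-instruction
delay-match/S1 segment overlap limits identifiability as described
above.  The acceptance machinery reports quantities the package itself
computes on synthetic data; no claim is made that the group-level F
values of any particular experiment are reproduced.
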