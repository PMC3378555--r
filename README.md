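# retinowm

Simulation and analysis of how task instructions redistribute
delay-period activity across the retinotopic maps of early visual
cortex.

In a two-stimulus spatial working-memory task, a dot position must be
held in mind and compared with a second dot either *categorically* (does
it appear in the diagonally opposite quadrant of a central cross?) or
*coordinately* (is it at the same distance from the centre, regardless
of quadrant?).  If attention rehearses the region where a match would
occur, delay-period BOLD activity in the parts of V1/V2/V3 that
represent the *matching* region — the opposite quadrant, or the ring at
the memorised radius — should exceed activity in the parts representing
the *mismatching* region, and the two instructions may distribute that
activity differently.

`retinowm` is aimed at methodologists who want this measurement chain as
tested, reusable code: it provides phase-encoded retinotopy (peak
cross-correlation over the 100 lags of a 54,000 ms / 540 ms cycle),
visual-field segment ROIs (quadrants and eccentricity rings), the
concatenated-segment delay-period GLM, and the repeated-measures group
statistics — plus a synthetic-data generator with known ground truth
(retinotopic voxel sheets, wedge/ring mapping runs, 80-trial task
sessions with injectable delay effects), so every stage is testable and
calibratable without any data download.

## The model in brief

For one visual area, the mean time courses of the four visual-field
segments are concatenated into a single series of length 4T and fitted
jointly by OLS:

```
y_concat = β_dm · X_delay-match + β_dmm · X_delay-mismatch
         + β_s1 · X_S1 + β_s2 · X_S2 + β_ecc · X_ecc-mod
         + per-block constants + per-block DCT drift + ε
```

where each regressor is HRF-convolved within the segment block in which
the trial logic expects that activation: delay boxcars (S1 offset → S2
onset) in each trial's matching / mismatching segment blocks, stimulus
impulses in the stimulated segment's block, and an
eccentricity-modulated copy of the stimulus events absorbing cortical
magnification.  Delay betas then enter a fully within-subject
area × instruction × region repeated-measures ANOVA (univariate and
multivariate variants), per-area follow-ups, and a contrast-activation
reliability check of the segment definitions.  Voxel phases come from
the peak Pearson correlation between each voxel's filtered series and a
cyclic activation regressor evaluated at every lag of the cycle, with
Bonferroni masking over voxels × lags.

## Worked example

Simulate one subject's wedge mapping run, recover the retinotopy, then
fit the delay GLM of a categorical session with a known injected effect
(match amplitude 0.3, mismatch 0.1 signal units):

```r
library(retinowm)

proto <- mappingProtocol()
sheet <- generateVoxelSheet(nPerArea = 64, proto, seed = 1)
wedge <- simulateMappingSeries(sheet, proto, "wedge",
                               effectSpec(mappingAmp = 3), seed = 2)
est   <- significanceMask(crosscorrMap(dctHighpass(wedge), proto))
segQ  <- assignPolarSegments(est)

pos     <- generateStimulusPositions(proto)
trials  <- generateTrialSequence("categorical", pos, seed = 3)
eff     <- effectSpec(delayMatchAmp = 0.3, delayMismatchAmp = 0.1)
series  <- simulateTaskSeries(sheet, trials, eff, seed = 4)
regions <- resolveRegions(trials)
design  <- buildConcatenatedDesign(trials, regions, nVolumes(series), 1500)
fitGlm(extractSegmentTimecourses(series, segQ, "V3"), design)
```

which prints (exactly; the pipeline is deterministic given seeds):

```
significant voxels: 192/192; correct quadrant: 100.0%
          factor   beta      se
1    delay_match 0.3060 0.00559
2 delay_mismatch 0.0963 0.00406
3             s1 0.3809 0.01783
4             s2 0.3895 0.01912
5        ecc_mod 0.0161 0.00600
```

All 192 voxels pass the Bonferroni mask and land in their true quadrant;
the delay betas recover the injected 0.3 / 0.1 within their standard
errors (the stimulus betas sit near amplitude/4 because a stimulated
quadrant × ring cell holds a quarter of its quadrant's voxels).  A
whole cohort plus group statistics and a markdown report is one call:

```r
runPipeline(readRunConfig(), outDir = "run1", seed = 1)
```

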