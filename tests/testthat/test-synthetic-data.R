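test_that("voxel sheets tile every quadrant x ring cell of every area", {
  expect_error(generateVoxelSheet(15, proto), "at least 16")

  sheet <- generateVoxelSheet(16, proto, seed = 3)
  v <- voxelData(sheet)
  expect_equal(nVoxels(sheet), 48L)
  occ <- table(v$area, v$quadrant, v$ring)
  expect_true(all(occ == 1L))  # minimal tiling: one voxel per cell

  sheet <- generateVoxelSheet(160, proto, seed = 1)
  v <- voxelData(sheet)
  expect_equal(nVoxels(sheet), 480L)
  expect_true(all(table(v$area, v$quadrant, v$ring) >= 10))
  expect_true(all(v$polar_deg >= 0 & v$polar_deg < 360))
  expect_true(all(v$ecc_deg > 0 & v$ecc_deg <= proto@ringMaxEcc))
  # ground-truth quadrant matches the polar angle it was drawn in
  expect_equal(v$quadrant, findInterval(v$polar_deg, c(0, 90, 180, 270)))

  # ring-1 occupancy by brute-force re-binning of the emitted eccentricities
  mids <- c(2.8125, 4.6875, 6.5625)
  for (a in c("V1", "V2", "V3")) {
    va <- v[v$area == a, ]
    expect_equal(sum(va$ecc_deg <= mids[1]), sum(va$ring == 1))
  }

  # deterministic given the seed
  expect_identical(voxelData(generateVoxelSheet(32, proto, seed = 9)),
                   voxelData(generateVoxelSheet(32, proto, seed = 9)))
})

test_that("the forty stimulus positions cover quadrants and radii evenly", {
  pos <- generateStimulusPositions(proto)
  expect_equal(nrow(pos), 40L)
  expect_equal(unname(table(pos$quadrant)), rep(10L, 4), ignore_attr = TRUE)
  expect_equal(sort(unique(pos$radius_deg)), c(1.875, 3.75, 5.625, 7.5))
  # never on a cross arm
  expect_true(all(pos$angle_deg %% 90 != 0))
  expect_true(all(pos$angle_deg > 90 * (pos$quadrant - 1) &
                    pos$angle_deg < 90 * pos$quadrant))
  expect_false(any(duplicated(pos[, c("quadrant", "ring", "angle_deg")])))
})

test_that("trial sequences respect composition, match rules and timing", {
  pos <- generateStimulusPositions(proto)
  expect_error(generateTrialSequence("spatial", pos), "arg")
  for (seed in 1:4) {
    for (ins in c("categorical", "coordinate")) {
      tr <- generateTrialSequence(ins, pos, seed = seed)
      expect_equal(nrow(tr), 80L)
      expect_equal(sum(tr$trial_type == "match"), 40L)
      expect_equal(sum(tr$trial_type == "nonmatch"), 30L)
      expect_equal(sum(tr$trial_type == "catch"), 10L)
      # every position serves as S1 exactly twice
      expect_true(all(table(tr$s1_position) == 2L))
      # jitter on the 1000 ms grid within the stated range
      expect_true(all(tr$jitter_ms >= 3000 & tr$jitter_ms <= 8000))
      expect_true(all(tr$jitter_ms %% 1000 == 0))
      # catch trials have no second stimulus and no required response
      catch <- tr$trial_type == "catch"
      expect_true(all(is.na(tr$s2_onset_ms[catch])))
      expect_true(all(tr$correct_response[catch] == "none"))
      # match rule, checked exhaustively per trial
      mt <- tr[tr$trial_type == "match", ]
      nm <- tr[tr$trial_type == "nonmatch", ]
      if (ins == "categorical") {
        expect_true(all(mt$s2_quadrant == (mt$s1_quadrant + 1) %% 4 + 1))
        expect_true(all(nm$s2_quadrant != (nm$s1_quadrant + 1) %% 4 + 1))
      } else {
        expect_true(all(mt$s2_ring == mt$s1_ring))
        expect_true(all(nm$s2_ring != nm$s1_ring))
      }
      # trial schematic: S2 follows S1 by 300 ms plus the jitter
      ok <- !catch
      expect_equal(tr$s2_onset_ms[ok], tr$s1_onset_ms[ok] + 300 +
                     tr$jitter_ms[ok])
      expect_true(all(diff(tr$s1_onset_ms) > 0))
    }
  }
  expect_identical(generateTrialSequence("categorical", pos, seed = 11),
                   generateTrialSequence("categorical", pos, seed = 11))
})

test_that("mapping simulation has protocol-implied length and periodicity", {
  sheet <- makeLagSheet(c(0, 25, 50))
  run <- simulateMappingSeries(sheet, proto, "wedge", noiselessEffects(),
                               seed = 1)
  expect_equal(nVolumes(run), 900L)  # (8*54000 + 2*27000) / 540
  X <- assay(run, "bold")
  # noiseless voxel time course is cycle-periodic after the first cycle
  cyc <- 100L; blank <- 50L
  c2 <- X[, blank + cyc + seq_len(cyc)]
  c5 <- X[, blank + 4 * cyc + seq_len(cyc)]
  expect_equal(c2, c5, tolerance = 1e-12)
  # voxels half a cycle apart are circularly shifted copies of each other
  inCycles <- blank + seq_len(8 * cyc)
  shifted <- matrix(X[3, inCycles], nrow = cyc)  # columns = cycles
  base <- matrix(X[1, inCycles], nrow = cyc)
  rolled <- rbind(base[(50 + 1):cyc, , drop = FALSE],
                  base[seq_len(50), , drop = FALSE])
  # compare away from the first cycle where the blank breaks periodicity
  expect_equal(shifted[, 3:8], rolled[, 3:8], tolerance = 1e-12)
  # determinism and seed separation: the noiseless part is noise-invariant
  run2 <- simulateMappingSeries(sheet, proto, "wedge", noiselessEffects(),
                                seed = 99)
  expect_identical(assay(run, "bold"), assay(run2, "bold"))
})

test_that("task simulation places delay activity in the instructed region", {
  sheet <- generateVoxelSheet(16, proto, seed = 4, noiseSd = 0)
  v <- voxelData(sheet)

  # null delay effect: signal confined to HRF-smeared S1/S2 windows
  tr <- makeTrials("categorical", s1q = 3, s1r = 2, trialType = "match",
                   s2q = 1, s2r = 2)
  eff <- noiselessEffects(ampS1 = 1, ampS2 = 1, delayMatchAmp = 0,
                          delayMismatchAmp = 0)
  ser <- simulateTaskSeries(sheet, tr, eff, seed = 1, volumeMs = 1500)
  X <- assay(ser, "bold")
  tmid <- (seq_len(ncol(X)) - 0.5) * 1500
  inWindow <- (tmid >= tr$s1_onset_ms & tmid <= tr$s1_onset_ms + 33000) |
    (tmid >= tr$s2_onset_ms & tmid <= tr$s2_onset_ms + 33000)
  expect_true(all(abs(X[, !inWindow]) < 1e-12))
  # S1/S2 responses only in the stimulated cells
  stim <- (v$quadrant == 3 & v$ring == 2) | (v$quadrant == 1 & v$ring == 2)
  expect_true(all(abs(X[!stim, ]) < 1e-12))
  expect_true(all(rowSums(abs(X[stim, ])) > 0))

  # categorical: only the opposite quadrant carries the match delay signal
  effD <- noiselessEffects(ampS1 = 0, ampS2 = 0, delayMatchAmp = 1,
                           delayMismatchAmp = 0)
  serD <- simulateTaskSeries(sheet, tr, effD, seed = 1, volumeMs = 1500)
  active <- rowSums(abs(assay(serD, "bold"))) > 0
  expect_setequal(which(active), which(v$quadrant == 1))

  # coordinate: the matching ring across all four quadrants
  trc <- makeTrials("coordinate", s1q = 3, s1r = 2, trialType = "match",
                    s2q = 2, s2r = 2)
  serC <- simulateTaskSeries(sheet, trc, effD, seed = 1, volumeMs = 1500)
  activeC <- rowSums(abs(assay(serC, "bold"))) > 0
  expect_setequal(which(activeC), which(v$ring == 2))
})

test_that("behavioural generator matches its stated probabilities", {
  pos <- generateStimulusPositions(proto)
  tr <- generateTrialSequence("categorical", pos, seed = 2)
  beh <- simulateBehavior(tr, accByInstruction = c(categorical = 1,
                                                   coordinate = 1),
                          seed = 1)
  expect_equal(nrow(beh), 70L)           # catch trials are never scored
  expect_true(all(beh$correct))
  expect_true(all(beh$rt_ms > 0))
  expect_false(any(beh$trial_type == "catch"))
  expect_error(simulateBehavior(tr, accByInstruction = c(categorical = 0)),
               "accuracy")

  # Monte-Carlo calibration against the binomial expectation
  hits <- vapply(1:400, function(s)
    sum(simulateBehavior(tr, accByInstruction = c(categorical = 0.5),
                         seed = s)$correct), numeric(1))
  expect_lt(abs(mean(hits) / 70 - 0.5), 0.01)
})
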