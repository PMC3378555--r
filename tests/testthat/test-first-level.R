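test_that("segment extraction averages voxels and concatenates in order", {
  sheet <- generateVoxelSheet(16, proto, seed = 2, noiseSd = 0)
  tr <- makeTrials("categorical", s1q = 1, s1r = 1, trialType = "catch")
  eff <- noiselessEffects(ampS1 = 1)
  ser <- simulateTaskSeries(sheet, tr, eff, seed = 1, volumeMs = 1500)
  segmap <- gtSegmap(sheet, "quadrant")
  tcs <- extractSegmentTimecourses(ser, segmap, "V1")
  T <- nVolumes(ser)
  expect_equal(length(concatTimecourse(tcs)), 4L * T)
  expect_equal(concatTimecourse(tcs)[seq_len(T)], tcs@segMeans[, 1])

  # the mean over a segment equals the hand-computed voxel mean
  v <- voxelData(sheet)
  q2 <- v$voxel_id[v$area == "V1" & v$quadrant == 2]
  expect_equal(tcs@segMeans[, 2],
               colMeans(assay(ser, "bold")[q2, , drop = FALSE]))

  # duplicating every voxel leaves the means unchanged
  v2 <- rbind(v, v); v2$voxel_id <- seq_len(nrow(v2))
  sheet2 <- new("VoxelSheet", voxels = v2, maxEcc = proto@ringMaxEcc)
  ser2 <- simulateTaskSeries(sheet2, tr, eff, seed = 1, volumeMs = 1500)
  tcs2 <- extractSegmentTimecourses(ser2, gtSegmap(sheet2, "quadrant"),
                                    "V1")
  expect_equal(tcs2@segMeans, tcs@segMeans)

  # an empty segment is reported by name
  vShort <- v[!(v$area == "V1" & v$quadrant == 3), ]
  sheet3 <- new("VoxelSheet", voxels = vShort, maxEcc = proto@ringMaxEcc)
  ser3 <- simulateTaskSeries(sheet3, tr, eff, seed = 1, volumeMs = 1500)
  expect_error(
    extractSegmentTimecourses(ser3, gtSegmap(sheet3, "quadrant"), "V1"),
    "segment 3")
})

test_that("design columns live only in the blocks the trial logic implies", {
  # single categorical trial, S1 in Q3: match activity modelled in block 1
  tr <- makeTrials("categorical", s1q = 3, s1r = 2, trialType = "match",
                   s2q = 1, s2r = 3)
  reg <- resolveRegions(tr)
  T <- 20L
  idk <- identityKernel(1500)
  des <- buildConcatenatedDesign(tr, reg, T, 1500, hrf = idk)
  X <- designMatrix(des)
  block <- rep(1:4, each = T)
  dm <- X[, "delay_match"]
  expect_true(all(dm[block != 1] == 0))
  tmid <- (seq_len(T) - 0.5) * 1500
  inDelay <- tmid >= tr$s1_onset_ms + 300 & tmid < tr$s2_onset_ms
  expect_equal(dm[block == 1] > 0, inDelay)
  expect_true(all(X[, "delay_mismatch"][!block %in% c(2, 4)] == 0))
  expect_true(all(X[, "s1"][block != 3] == 0))
  expect_true(all(X[, "s2"][block != 1] == 0))

  # zero trials: only constants and high-pass columns remain
  suppressMessages(
    d0 <- buildConcatenatedDesign(tr[0, ], resolveRegions(tr[0, ]), T,
                                  1500, hrf = idk))
  expect_length(d0@neuralColumns, 0L)
  expect_equal(ncol(designMatrix(d0)), 4L * 9L)  # constants + 8 DCT each
})

test_that("design support matches an independent brute-force placement", {
  pos <- generateStimulusPositions(proto)
  for (ins in c("categorical", "coordinate")) {
    tr <- generateTrialSequence(ins, pos, seed = 5)
    reg <- resolveRegions(tr)
    T <- sessionVolumes(tr, 1500)
    idk <- identityKernel(1500)
    X <- designMatrix(buildConcatenatedDesign(tr, reg, T, 1500, hrf = idk))
    mode <- reg$mode[1]
    segcol <- if (mode == "quadrant") "quadrant" else "ring"
    tmid <- (seq_len(T) - 0.5) * 1500
    # naive per-volume membership, recomputed from the trial table alone
    naive <- matrix(0, 4 * T, 4,
                    dimnames = list(NULL, c("delay_match", "delay_mismatch",
                                            "s1", "s2")))
    for (b in 1:4) {
      rows <- (b - 1) * T + seq_len(T)
      for (i in seq_len(nrow(tr))) {
        s1s <- tr[[paste0("s1_", segcol)]][i]
        s2s <- tr[[paste0("s2_", segcol)]][i]
        catch <- tr$trial_type[i] == "catch"
        dStart <- tr$s1_onset_ms[i] + 300
        dEnd <- if (catch) dStart + 5500 else tr$s2_onset_ms[i]
        matchSeg <- if (ins == "categorical")
          (s1s + 1) %% 4 + 1 else s1s
        mismSegs <- if (ins == "categorical")
          setdiff(1:4, c(matchSeg, s1s)) else setdiff(1:4, matchSeg)
        inD <- tmid >= dStart & tmid < dEnd
        if (b == matchSeg) naive[rows, "delay_match"] <-
            naive[rows, "delay_match"] + inD
        if (b %in% mismSegs) naive[rows, "delay_mismatch"] <-
            naive[rows, "delay_mismatch"] + inD
        if (b == s1s) {
          j <- floor(tr$s1_onset_ms[i] / 1500) + 1
          naive[rows[j], "s1"] <- naive[rows[j], "s1"] + 1
        }
        if (!catch && b == s2s) {
          j <- floor(tr$s2_onset_ms[i] / 1500) + 1
          naive[rows[j], "s2"] <- naive[rows[j], "s2"] + 1
        }
      }
    }
    for (nm in colnames(naive))
      expect_equal(X[, nm], naive[, nm], ignore_attr = TRUE)
  }
})

test_that("injected amplitudes are recovered exactly without noise", {
  sheet <- generateVoxelSheet(32, proto, seed = 2, noiseSd = 0)
  pos <- generateStimulusPositions(proto)
  eff <- noiselessEffects(ampS1 = 1.5, ampS2 = 1.2, delayMatchAmp = 0.4,
                          delayMismatchAmp = 0.15, eccAmp = 0.2)
  truth <- c(delay_match = 0.4, delay_mismatch = 0.15, s1 = 1.5 / 4,
             s2 = 1.2 / 4, ecc_mod = 0.2 / 4)
  for (ins in c("categorical", "coordinate")) {
    tr <- generateTrialSequence(ins, pos, seed = 3)
    ser <- simulateTaskSeries(sheet, tr, eff, seed = 1, volumeMs = 1500)
    reg <- resolveRegions(tr)
    segmap <- gtSegmap(sheet, reg$mode[1])
    des <- buildConcatenatedDesign(tr, reg, nVolumes(ser), 1500)
    for (a in c("V1", "V2", "V3")) {
      fit <- fitGlm(extractSegmentTimecourses(ser, segmap, a), des)
      got <- stats::setNames(fit$beta, fit$factor)[names(truth)]
      expect_equal(unname(got), unname(truth), tolerance = 1e-6)
    }
  }
})

test_that("equal match and mismatch amplitudes yield a null difference", {
  sheet <- generateVoxelSheet(32, proto, seed = 8, noiseSd = 1)
  pos <- generateStimulusPositions(proto)
  eff <- effectSpec(delayMatchAmp = 0.2, delayMismatchAmp = 0.2,
                    ar1Rho = 0.3, driftCoeffs = c(0.5, 0.5))
  tr <- generateTrialSequence("categorical", pos, seed = 4)
  ser <- simulateTaskSeries(sheet, tr, eff, seed = 21, volumeMs = 1500)
  reg <- resolveRegions(tr)
  des <- buildConcatenatedDesign(tr, reg, nVolumes(ser), 1500)
  fit <- fitGlm(extractSegmentTimecourses(ser, gtSegmap(sheet, "quadrant"),
                                          "V2"), des)
  b <- stats::setNames(fit$beta, fit$factor)
  se <- stats::setNames(fit$se, fit$factor)
  expect_lt(abs(b["delay_match"] - b["delay_mismatch"]),
            3 * sqrt(se["delay_match"]^2 + se["delay_mismatch"]^2))
})

test_that("replicate fits are unbiased under noise", {
  tpl <- sessionTemplate(seed = 2)
  b <- simulateCohortDelayBetas(tpl, nSubjects = 150,
                                delayMatchAmp = 0.3,
                                delayMismatchAmp = 0.1, noiseSd = 1,
                                ar1Rho = 0.3, seed = 9, areas = "V1")
  dm <- b$beta[b$region == "match" & b$instruction == "categorical"]
  dmm <- b$beta[b$region == "mismatch" & b$instruction == "categorical"]
  expect_lt(abs(mean(dm) - 0.3), 0.05 * 0.3)
  expect_lt(abs(mean(dmm) - 0.1), 0.05 * 0.3)
  # estimator spread scales with the noise level
  b2 <- simulateCohortDelayBetas(tpl, nSubjects = 150, noiseSd = 2,
                                 ar1Rho = 0.3, seed = 9, areas = "V1")
  dm2 <- b2$beta[b2$region == "match" & b2$instruction == "categorical"]
  expect_gt(sd(dm2), 1.5 * sd(dm))
})

test_that("stimulus-split betas behave under degeneracy, null and scaling", {
  sheet <- generateVoxelSheet(32, proto, seed = 2, noiseSd = 0)
  pos <- generateStimulusPositions(proto)
  tr <- generateTrialSequence("categorical", pos, seed = 3)
  reg <- resolveRegions(tr)
  segmap <- gtSegmap(sheet, "quadrant")

  eff <- noiselessEffects(ampS1 = 1.5, ampS2 = 1.2)
  ser <- simulateTaskSeries(sheet, tr, eff, seed = 1, volumeMs = 1500)
  tcs <- extractSegmentTimecourses(ser, segmap, "V1")
  sb <- stimulusBetas(tcs, tr, reg)
  expect_setequal(sb$factor, c("s1", "s2_match", "s2_mismatch"))
  # equal injected S2 amplitude: both S2 betas recover it exactly
  expect_equal(sb$beta[sb$factor == "s2_match"], 1.2 / 4, tolerance = 1e-6)
  expect_equal(sb$beta[sb$factor == "s2_mismatch"], 1.2 / 4,
               tolerance = 1e-6)
  # linear in the injected amplitude
  eff2 <- noiselessEffects(ampS1 = 1.5, ampS2 = 2.4)
  ser2 <- simulateTaskSeries(sheet, tr, eff2, seed = 1, volumeMs = 1500)
  sb2 <- stimulusBetas(extractSegmentTimecourses(ser2, segmap, "V1"), tr,
                       reg)
  expect_equal(sb2$beta[sb2$factor == "s2_match"],
               2 * sb$beta[sb$factor == "s2_match"], tolerance = 1e-6)

  # all-match session: the mismatch column is empty, flagged and dropped
  keep <- tr$trial_type != "nonmatch"
  trM <- tr[keep, ]; attr(trM, "sessionEndMs") <- attr(tr, "sessionEndMs")
  serM <- simulateTaskSeries(sheet, trM, eff, seed = 1, volumeMs = 1500)
  expect_warning(
    sbM <- stimulusBetas(extractSegmentTimecourses(serM, segmap, "V1"),
                         trM, resolveRegions(trM)),
    "s2_mismatch")
  expect_false("s2_mismatch" %in% sbM$factor)
})

test_that("contrast activation isolates the stimulated segment", {
  sheet <- generateVoxelSheet(32, proto, seed = 2, noiseSd = 0)
  pos <- generateStimulusPositions(proto)
  tr <- generateTrialSequence("categorical", pos, seed = 3)
  eff <- noiselessEffects(ampS1 = 2, ampS2 = 2)
  ser <- simulateTaskSeries(sheet, tr, eff, seed = 1, volumeMs = 1500)
  for (m in c("quadrant", "ring")) {
    tcs <- extractSegmentTimecourses(ser, gtSegmap(sheet, m), "V2")
    ca <- contrastActivation(tcs, tr, m)
    # response confined to its own segment: contrast = amplitude / 4
    expect_equal(ca$value, 2 / 4, tolerance = 1e-6)
    expect_equal(ca$perGroup$contrast, rep(0.5, 4), tolerance = 1e-6)
  }

  # a spatially uniform response nulls the contrast
  cd <- buildContrastDesign(tr, "quadrant",
                            sessionVolumes(tr, 1500), 1500)
  X <- designMatrix(cd$design)
  y <- rowSums(X[, cd$design@neuralColumns])  # same response in all blocks
  tcsU <- new("SegmentTimecourses", area = "V1", mode = "quadrant",
              segMeans = matrix(y, ncol = 4), volumeMs = 1500)
  caU <- contrastActivation(tcsU, tr, "quadrant")
  expect_equal(caU$value, 0, tolerance = 1e-8)
})
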