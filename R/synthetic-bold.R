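# voxel noise: white Gaussian innovations passed through an AR(1) recursion,
# scaled so the stated noise_sd is the marginal SD
makeNoise <- function(noiseSd, nVol, ar1Rho) {
  nVox <- length(noiseSd)
  innovSd <- if (ar1Rho > 0) sqrt(1 - ar1Rho^2) else 1
  E <- matrix(stats::rnorm(nVox * nVol), nrow = nVol, ncol = nVox)
  if (ar1Rho > 0)
    E <- apply(E, 2, function(e)
      as.numeric(stats::filter(e, ar1Rho, method = "recursive")))
  t(E) * (noiseSd * innovSd)
}

# slow drift shared by all voxels: linear ramp plus a half-cosine over the run
makeDrift <- function(coeffs, nVol) {
  lin <- seq(-0.5, 0.5, length.out = nVol)
  cosine <- cos(pi * (seq_len(nVol) - 1) / (nVol - 1))
  coeffs[1] * lin + coeffs[2] * cosine
}

#' Simulate a phase-encoded retinotopic mapping run
#'
#' Each voxel's neural drive is a periodic boxcar that switches on when the
#' mapping stimulus reaches the voxel's receptive field -- the wedge's
#' leading edge crossing its polar angle, or the expanding ring's centre
#' crossing its eccentricity -- and stays on for the protocol's per-cycle
#' activation duration.  The drive is zero during the blank lead and trail,
#' convolved with the HRF, scaled by \code{gain * mappingAmp}, and
#' completed with drift and AR(1) Gaussian noise.  With
#' \code{noise_sd = 0} and zero drift the run is a noiseless oracle whose
#' phase is exactly recoverable.
#'
#' @param sheet a [VoxelSheet-class].
#' @param protocol a [MappingProtocol-class].
#' @param stimulus \code{"wedge"} (polar angle) or \code{"ring"}
#'   (eccentricity).
#' @param effects an [EffectSpec-class]; uses \code{mappingAmp},
#'   \code{ar1Rho} and \code{driftCoeffs}.
#' @param seed integer seed for the noise.
#' @param hrf optional [HrfKernel-class] at the protocol's volume interval.
#' @return a [BoldSeries-class] with \code{nVolumes(protocol)} volumes.
#' @export
simulateMappingSeries <- function(sheet, protocol = mappingProtocol(),
                                  stimulus = c("wedge", "ring"),
                                  effects = effectSpec(), seed = 1L,
                                  hrf = NULL) {
  stimulus <- match.arg(stimulus)
  if (protocol@cycleMs %% protocol@volumeMs != 0)
    stop("cycleMs must be divisible by volumeMs")
  if (is.null(hrf)) hrf <- canonicalHrf(protocol@volumeMs)
  v <- voxelData(sheet)
  tOn <- if (stimulus == "wedge") {
    ((v$polar_deg - protocol@startAngleDeg) %% 360) / 360 * protocol@cycleMs
  } else {
    c0 <- ringEccStart(protocol)
    ((v$ecc_deg - c0) / (protocol@ringMaxEcc - c0) * protocol@cycleMs) %%
      protocol@cycleMs
  }
  drive <- t(vapply(tOn, function(t0)
    convolveHrf(cyclicDrive(t0, protocol), hrf), numeric(nVolumes(protocol))))
  signal <- drive * (v$gain * effects@mappingAmp)
  withr::local_seed(seed)
  nVol <- ncol(signal)
  signal <- signal +
    matrix(makeDrift(effects@driftCoeffs, nVol), nrow(signal), nVol,
           byrow = TRUE) +
    makeNoise(v$noise_sd, nVol, effects@ar1Rho)
  boldSeries(signal, protocol@volumeMs, sheet = sheet,
             sessionType = "mapping", stimulus = stimulus)
}

#' Simulate a working-memory task session
#'
#' Embodies the attentional-rehearsal model the delay-period GLM is built
#' to test.  Transient HRF responses to S1 and S2 are added to voxels of
#' the stimulated quadrant x ring cell (with an optional
#' eccentricity-proportional component, \code{eccAmp}); during every
#' retention interval a sustained boxcar of amplitude
#' \code{delayMatchAmp} is added to voxels of the region that would match
#' the first stimulus under the session's instruction (the diagonally
#' opposite quadrant, or the same eccentricity ring across all quadrants),
#' and \code{delayMismatchAmp} to the mismatching region.  Catch trials
#' contribute an S1 response and a delay period truncated at the modeled
#' S2 time of a median-jitter trial, but no S2.  Event placement and HRF
#' convolution reuse the same regressor constructors as the analysis
#' design, so noiseless simulations are exactly representable by the GLM.
#'
#' @param sheet a [VoxelSheet-class].
#' @param trials trial table from [generateTrialSequence()].
#' @param effects an [EffectSpec-class].
#' @param seed integer seed for the noise.
#' @param volumeMs acquisition interval of the task session in ms
#'   (default 1500).
#' @param hrf optional [HrfKernel-class] at \code{volumeMs}.
#' @return a [BoldSeries-class]; its metadata records the instruction and
#'   the trial table.
#' @export
simulateTaskSeries <- function(sheet, trials, effects = effectSpec(),
                               seed = 1L, volumeMs = 1500, hrf = NULL) {
  if (is.null(hrf)) hrf <- canonicalHrf(volumeMs)
  v <- voxelData(sheet)
  nVol <- sessionVolumes(trials, volumeMs)
  instruction <- trials$instruction[1]
  regions <- resolveRegions(trials)
  dw <- delayWindow(trials)
  rbar <- eventRadiusMean(trials)
  tt <- trialTiming()

  cellOf <- function(q, r) (r - 1L) * 4L + q
  S1 <- S2 <- EC <- matrix(0, 16L, nVol)
  for (q in 1:4) for (r in 1:4) {
    k <- cellOf(q, r)
    i1 <- which(trials$s1_quadrant == q & trials$s1_ring == r)
    i2 <- which(!is.na(trials$s2_onset_ms) &
                  trials$s2_quadrant == q & trials$s2_ring == r)
    if (length(i1))
      S1[k, ] <- eventRegressor(trials$s1_onset_ms[i1], 0, nVol, volumeMs,
                                hrf)
    if (length(i2))
      S2[k, ] <- eventRegressor(trials$s2_onset_ms[i2], 0, nVol, volumeMs,
                                hrf)
    eccOn <- c(trials$s1_onset_ms[i1], trials$s2_onset_ms[i2])
    eccW <- c(trials$s1_radius[i1], trials$s2_radius[i2]) - rbar
    if (length(eccOn))
      EC[k, ] <- eventRegressor(eccOn, 0, nVol, volumeMs, hrf,
                                weights = eccW)
  }
  DM <- DMM <- matrix(0, 4L, nVol)
  for (s in 1:4) {
    im <- which(regions$matching_segment == s)
    imm <- which(vapply(regions$mismatching_segments,
                        function(m) s %in% m, logical(1)))
    if (length(im))
      DM[s, ] <- eventRegressor(dw$start_ms[im],
                                dw$end_ms[im] - dw$start_ms[im],
                                nVol, volumeMs, hrf)
    if (length(imm))
      DMM[s, ] <- eventRegressor(dw$start_ms[imm],
                                 dw$end_ms[imm] - dw$start_ms[imm],
                                 nVol, volumeMs, hrf)
  }
  cellIdx <- cellOf(v$quadrant, v$ring)
  segIdx <- if (instruction == "categorical") v$quadrant else v$ring
  dmA <- vapply(v$area, function(a) areaAmp(effects@delayMatchAmp, a),
                numeric(1))
  dmmA <- vapply(v$area, function(a) areaAmp(effects@delayMismatchAmp, a),
                 numeric(1))
  signal <- effects@ampS1 * S1[cellIdx, , drop = FALSE] +
    effects@ampS2 * S2[cellIdx, , drop = FALSE] +
    effects@eccAmp * EC[cellIdx, , drop = FALSE] +
    DM[segIdx, , drop = FALSE] * dmA +
    DMM[segIdx, , drop = FALSE] * dmmA
  signal <- signal * v$gain
  withr::local_seed(seed)
  signal <- signal +
    matrix(makeDrift(effects@driftCoeffs, nVol), nrow(signal), nVol,
           byrow = TRUE) +
    makeNoise(v$noise_sd, nVol, effects@ar1Rho)
  boldSeries(signal, volumeMs, sheet = sheet, sessionType = "task",
             extra = list(instruction = instruction, trials = trials))
}

# mean eccentricity over all presented stimuli of a session (the centring
# constant of the eccentricity modulator)
eventRadiusMean <- function(trials) {
  mean(c(trials$s1_radius,
         trials$s2_radius[!is.na(trials$s2_onset_ms)]))
}
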