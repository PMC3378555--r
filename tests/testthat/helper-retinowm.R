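# shared fixtures, all generated in code

proto <- mappingProtocol()

noiselessEffects <- function(...)
  effectSpec(ar1Rho = 0, driftCoeffs = c(0, 0), ...)

# sheet of voxels sitting exactly on the given cross-correlation lag bins
# (both in polar angle and in eccentricity), for exact phase-recovery tests
makeLagSheet <- function(lags, protocol = proto, noiseSd = 0, gain = 1) {
  vox <- S4Vectors::DataFrame(
    voxel_id = seq_along(lags), area = "V1",
    quadrant = pmin(lagToPolar(lags, protocol) %/% 90 + 1L, 4L),
    ring = 1L,
    polar_deg = lagToPolar(lags, protocol),
    ecc_deg = lagToEccentricity(lags, protocol),
    gain = gain, noise_sd = noiseSd)
  new("VoxelSheet", voxels = vox, maxEcc = protocol@ringMaxEcc)
}

# estimates table carrying the sheet's ground-truth positions, for
# ground-truth segment maps
truthEstimates <- function(sheet) {
  v <- voxelData(sheet)
  data.frame(voxel_id = v$voxel_id, area = v$area,
             polar_deg = v$polar_deg, ecc_deg = v$ecc_deg, valid = TRUE)
}

gtSegmap <- function(sheet, mode = c("quadrant", "ring")) {
  mode <- match.arg(mode)
  if (mode == "quadrant") assignPolarSegments(truthEstimates(sheet))
  else assignEccSegments(truthEstimates(sheet))
}

# minimal hand-built trial table (one or more rows) with valid timing
makeTrials <- function(instruction, s1q, s1r, trialType = "match",
                       s2q = NA, s2r = NA, jitter = 5000) {
  n <- length(s1q)
  trialType <- rep_len(trialType, n)
  jitter <- rep_len(jitter, n)
  s2q <- rep_len(s2q, n); s2r <- rep_len(s2r, n)
  radii <- c(1.875, 3.75, 5.625, 7.5)
  s1on <- numeric(n); t0 <- 0
  for (i in seq_len(n)) {
    s1on[i] <- t0 + 1000
    t0 <- s1on[i] + 300 + jitter[i] + 300 + 2000 + 10000
  }
  catch <- trialType == "catch"
  tr <- data.frame(
    trial_id = seq_len(n), instruction = instruction,
    trial_type = trialType,
    s1_position = NA_integer_, s1_quadrant = s1q, s1_ring = s1r,
    s1_radius = radii[s1r], s1_angle = 90 * (s1q - 1) + 45,
    s2_position = NA_integer_, s2_quadrant = s2q, s2_ring = s2r,
    s2_radius = ifelse(is.na(s2r), NA_real_, radii[ifelse(is.na(s2r), 1,
                                                          s2r)]),
    s2_angle = ifelse(is.na(s2q), NA_real_, 90 * (s2q - 1) + 45),
    jitter_ms = jitter, s1_onset_ms = s1on,
    s2_onset_ms = ifelse(catch, NA_real_, s1on + 300 + jitter),
    correct_response = ifelse(catch, "none", trialType))
  attr(tr, "sessionEndMs") <- t0
  tr
}

# identity "HRF": turns convolved regressors into raw drives, so design
# support can be inspected directly
identityKernel <- function(samplingMs)
  new("HrfKernel",
      samples = c(1, rep(0, ceiling(30000 / samplingMs) + 1L)),
      samplingMs = samplingMs)
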