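#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma kernel (response gamma with shape 6, undershoot
#' gamma with shape 16, undershoot ratio 1/6, unit dispersion), sampled on
#' the volume grid and peak-normalised to 1.  The kernel value at t = 0 is
#' exactly 0 and the positive peak falls near 5 s.
#'
#' @param samplingMs sampling interval in ms (> 0).
#' @param lengthS kernel support in seconds (default 32).
#' @return an [HrfKernel-class] object.
#' @examples
#' h <- canonicalHrf(540)
#' which.max(h@samples)  # peak near 5 s
#' @export
canonicalHrf <- function(samplingMs, lengthS = 32) {
  stopifnot(samplingMs > 0)
  t <- seq(0, lengthS, by = samplingMs / 1000)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  new("HrfKernel", samples = h / max(h), samplingMs = samplingMs)
}

# Causal convolution of a regressor with an HRF kernel on a matching grid.
# Direct (non-FFT) accumulation over the nonzero drive samples: regressor
# drives are sparse, and the result is exact (no FFT round-off), which the
# noiseless-recovery oracles rely on.
convolveHrf <- function(x, hrf) {
  stopifnot(is(hrf, "HrfKernel"))
  h <- hrf@samples
  n <- length(x)
  y <- numeric(n)
  for (i in which(x != 0)) {
    idx <- i:min(n, i + length(h) - 1L)
    y[idx] <- y[idx] + x[i] * h[seq_along(idx)]
  }
  y
}

# Neural drive of a periodic on/off response with continuous onset phase
# tOnMs within the cycle.  A volume is "on" when its midpoint falls inside
# the activation window; this midpoint rule makes the number of active
# volumes per cycle equal round(onDurationMs / volumeMs) (13 for the
# defaults) independent of the lag.
cyclicDrive <- function(tOnMs, protocol) {
  nv <- nVolumes(protocol)
  tmid <- (seq_len(nv) - 0.5) * protocol@volumeMs
  tcyc <- tmid - protocol@blankMs
  inCycle <- tcyc >= 0 & tcyc < protocol@nCycles * protocol@cycleMs
  drive <- numeric(nv)
  drive[inCycle] <-
    as.numeric(((tcyc[inCycle] - tOnMs) %% protocol@cycleMs) <
                 protocol@onDurationMs)
  drive
}

#' Cyclic activation regressor for phase-encoded mapping
#'
#' Builds the regressor encoding periodic activation (on for
#' \code{onDurationMs} once per cycle) at a given lag, zero during the blank
#' lead and trail, convolved with the HRF.  Lags are expressed in volumes
#' within the cycle (0 to \code{lagsPerCycle(protocol) - 1}); incrementing
#' the lag circularly shifts the pre-convolution pattern within each cycle.
#'
#' @param protocol a [MappingProtocol-class].
#' @param lag integer lag in volumes, in 0..lagsPerCycle-1.
#' @param hrf an [HrfKernel-class] sampled at the protocol's volume
#'   interval; defaults to [canonicalHrf()].
#' @param convolved if \code{FALSE}, return the raw on/off drive.
#' @return numeric vector of length \code{nVolumes(protocol)}.
#' @examples
#' r <- cyclicRegressor(mappingProtocol(), lag = 0, convolved = FALSE)
#' sum(r) / 8  # 13 active volumes per cycle
#' @export
cyclicRegressor <- function(protocol, lag = 0L, hrf = NULL,
                            convolved = TRUE) {
  L <- lagsPerCycle(protocol)
  if (lag < 0 || lag >= L)
    stop("lag must lie in 0..", L - 1L)
  drive <- cyclicDrive(lag * protocol@volumeMs, protocol)
  if (!convolved) return(drive)
  if (is.null(hrf)) hrf <- canonicalHrf(protocol@volumeMs)
  stopifnot(hrf@samplingMs == protocol@volumeMs)
  convolveHrf(drive, hrf)
}

#' Event / boxcar regressor on a volume grid
#'
#' Places weighted events on the acquisition grid and convolves with the
#' HRF.  Zero-duration events are impulses assigned to the volume during
#' which they occur (\code{floor(onset / volumeMs)}); positive-duration
#' boxcars mark every volume whose midpoint falls inside
#' \code{[onset, onset + duration)}.  The regressor is linear in the event
#' weights and an empty onset list yields the zero regressor.
#'
#' @param onsetsMs event onset times in ms (session clock, first volume
#'   starts at 0).
#' @param durationsMs event durations in ms (0 = impulse); recycled.
#' @param nVolumes length of the target series in volumes.
#' @param volumeMs volume interval in ms.
#' @param hrf an [HrfKernel-class] sampled at \code{volumeMs}.
#' @param weights per-event amplitudes; recycled.
#' @param convolved if \code{FALSE}, return the unconvolved drive.
#' @return numeric vector of length \code{nVolumes}.
#' @export
eventRegressor <- function(onsetsMs, durationsMs = 0, nVolumes, volumeMs,
                           hrf = NULL, weights = 1, convolved = TRUE) {
  drive <- numeric(nVolumes)
  if (length(onsetsMs)) {
    durationsMs <- rep_len(durationsMs, length(onsetsMs))
    weights <- rep_len(weights, length(onsetsMs))
    sessionEnd <- nVolumes * volumeMs
    if (any(onsetsMs < 0 | onsetsMs >= sessionEnd))
      stop("event onset outside the series (0..", sessionEnd, " ms)")
    tmid <- (seq_len(nVolumes) - 0.5) * volumeMs
    for (i in seq_along(onsetsMs)) {
      if (durationsMs[i] <= 0) {
        idx <- floor(onsetsMs[i] / volumeMs) + 1L
        drive[idx] <- drive[idx] + weights[i]
      } else {
        on <- tmid >= onsetsMs[i] & tmid < onsetsMs[i] + durationsMs[i]
        drive[on] <- drive[on] + weights[i]
      }
    }
  }
  if (!convolved) return(drive)
  if (is.null(hrf)) hrf <- canonicalHrf(volumeMs)
  stopifnot(hrf@samplingMs == volumeMs)
  convolveHrf(drive, hrf)
}

#' Discrete-cosine high-pass basis
#'
#' The first \code{nBasis} non-constant columns of the orthonormal DCT-II
#' basis over \code{nVolumes} samples, lowest frequency first.  Together
#' with a constant these columns form the drift model regressed out of
#' every series; with the default of eight cosines over a T-volume run the
#' effective high-pass cutoff is 8 / (2 T dt) Hz.
#'
#' @param nVolumes series length in volumes.
#' @param nBasis number of cosine columns (default 8).
#' @return \code{nVolumes} x \code{nBasis} matrix with mutually orthonormal
#'   columns.
#' @export
dctBasis <- function(nVolumes, nBasis = 8L) {
  stopifnot(nBasis >= 1, nBasis < nVolumes)
  t <- seq_len(nVolumes)
  B <- vapply(seq_len(nBasis), function(k)
    sqrt(2 / nVolumes) * cos(pi * (2 * t - 1) * k / (2 * nVolumes)),
    numeric(nVolumes))
  colnames(B) <- paste0("dct", seq_len(nBasis))
  B
}

#' Remove low-frequency drift by DCT projection
#'
#' Residualises each voxel series against the constant plus the DCT
#' high-pass basis.  The output is orthogonal to the constant and to every
#' basis column, and the operation is idempotent.
#'
#' @param x a [BoldSeries-class], a voxel x volume matrix, or a numeric
#'   vector.
#' @param nBasis number of cosine columns (default 8).
#' @param basis optional pre-computed basis from [dctBasis()]; its row
#'   count must match the series length.
#' @return an object of the same type as \code{x}, drift-removed.
#' @export
dctHighpass <- function(x, nBasis = 8L, basis = NULL) {
  if (is(x, "BoldSeries")) {
    filtered <- dctHighpass(assay(x, "bold"), nBasis = nBasis, basis = basis)
    assay(x, "bold") <- filtered
    return(x)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  n <- ncol(m)
  if (is.null(basis)) basis <- dctBasis(n, nBasis)
  stopifnot(nrow(basis) == n)
  Q <- qr.Q(qr(cbind(1, basis)))
  res <- m - (m %*% Q) %*% t(Q)
  if (vec) as.vector(res) else res
}
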