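#' Phase mapping by lagged cross-correlation
#'
#' For every voxel, computes the Pearson correlation between its
#' (high-pass-filtered) time course and the cyclic activation regressor at
#' each of the \code{lagsPerCycle(protocol)} lags (100 for the default
#' protocol: every volume within a cycle), and takes the lag of the peak
#' correlation as the voxel's response phase.  Ties are broken towards the
#' smallest lag.  Because the regressor is HRF-convolved, the peak lag maps
#' directly onto stimulus phase -- polar angle for wedge runs via
#' [lagToPolar()], eccentricity for ring runs via [lagToEccentricity()] --
#' with no further delay correction.  p-values use the correlation
#' t-transform with \code{nVolumes - 2} degrees of freedom and do not
#' adjust for the selection of the best lag; [significanceMask()]
#' compensates by Bonferroni-correcting over voxels x lags by default.
#' Constant (zero-variance) voxel series are flagged invalid.
#'
#' @param series a [BoldSeries-class] mapping run (ideally already
#'   high-pass filtered with [dctHighpass()]).
#' @param protocol the [MappingProtocol-class] of the run.
#' @param hrf optional [HrfKernel-class] at the protocol's volume interval.
#' @param stimulus \code{"wedge"} or \code{"ring"}; defaults to the
#'   series' metadata.
#' @return data.frame with one row per voxel: \code{voxel_id},
#'   \code{area} (if present), \code{peak_lag} (0-based), \code{peak_r},
#'   \code{p_value}, the decoded \code{polar_deg} or \code{ecc_deg}, and
#'   \code{valid}.  The attributes \code{nLags} and \code{stimulus} record
#'   the lag grid and run type.
#' @export
crosscorrMap <- function(series, protocol = mappingProtocol(), hrf = NULL,
                         stimulus = NULL) {
  if (is.null(stimulus)) stimulus <- metadata(series)$stimulus
  stimulus <- match.arg(stimulus, c("wedge", "ring"))
  if (is.null(hrf)) hrf <- canonicalHrf(protocol@volumeMs)
  X <- t(assay(series, "bold"))          # volumes x voxels
  stopifnot(nrow(X) == nVolumes(protocol))
  L <- lagsPerCycle(protocol)
  R <- vapply(seq_len(L) - 1L, function(l)
    cyclicRegressor(protocol, l, hrf), numeric(nrow(X)))
  valid <- colSdsFast(X) > 0
  C <- matrix(NA_real_, ncol(X), L)
  if (any(valid)) C[valid, ] <- t(stats::cor(R, X[, valid, drop = FALSE]))
  peakLag <- rep(NA_integer_, ncol(X))
  peakR <- rep(NA_real_, ncol(X))
  peakLag[valid] <- max.col(C[valid, , drop = FALSE],
                            ties.method = "first") - 1L
  peakR[valid] <- C[cbind(which(valid), peakLag[valid] + 1L)]
  df <- nrow(X) - 2L
  tstat <- peakR * sqrt(df / pmax(1 - peakR^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  rd <- rowData(series)
  est <- data.frame(voxel_id = if ("voxel_id" %in% colnames(rd))
    rd$voxel_id else seq_len(ncol(X)))
  if ("area" %in% colnames(rd)) est$area <- rd$area
  est$peak_lag <- peakLag
  est$peak_r <- peakR
  est$p_value <- p
  if (stimulus == "wedge") {
    est$polar_deg <- NA_real_
    est$polar_deg[valid] <- lagToPolar(peakLag[valid], protocol)
  } else {
    est$ecc_deg <- NA_real_
    est$ecc_deg[valid] <- lagToEccentricity(peakLag[valid], protocol)
  }
  est$valid <- valid
  attr(est, "nLags") <- L
  attr(est, "stimulus") <- stimulus
  est
}

# column SDs without matrixStats; zero for constant columns
colSdsFast <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - m^2, 0) * n / (n - 1))
}

#' Convert between cross-correlation lag and visual-field position
#'
#' \code{lagToPolar} maps a wedge-run lag to the polar angle the wedge's
#' leading edge has reached after \code{lag} volumes:
#' \code{(startAngle + 360 * lag / L) mod 360} under the clockwise
#' convention (bin width 3.6 degrees for the default 100-lag grid).
#' \code{lagToEccentricity} maps a ring-run lag linearly in radius from the
#' ring's starting centre eccentricity (inner limit plus half a ring
#' width, 1.15 degrees by default) to the maximum eccentricity.
#' \code{polarToLag} and \code{eccentricityToLag} are the rounding
#' inverses.
#'
#' @param lag integer lag(s) in 0..lagsPerCycle-1.
#' @param protocol a [MappingProtocol-class].
#' @param polar,ecc positions in degrees.
#' @return degrees (or integer lags for the inverse functions).
#' @examples
#' lagToPolar(50, mappingProtocol())  # 180
#' @export
lagToPolar <- function(lag, protocol = mappingProtocol()) {
  L <- lagsPerCycle(protocol)
  if (any(lag < 0 | lag > L - 1)) stop("lag must lie in 0..", L - 1)
  (protocol@startAngleDeg + 360 * lag / L) %% 360
}

#' @rdname lagToPolar
#' @export
polarToLag <- function(polar, protocol = mappingProtocol()) {
  L <- lagsPerCycle(protocol)
  as.integer(round(((polar - protocol@startAngleDeg) %% 360) / (360 / L))) %% L
}

#' @rdname lagToPolar
#' @export
lagToEccentricity <- function(lag, protocol = mappingProtocol()) {
  L <- lagsPerCycle(protocol)
  if (any(lag < 0 | lag > L - 1)) stop("lag must lie in 0..", L - 1)
  c0 <- ringEccStart(protocol)
  c0 + (protocol@ringMaxEcc - c0) * lag / L
}

#' @rdname lagToPolar
#' @export
eccentricityToLag <- function(ecc, protocol = mappingProtocol()) {
  L <- lagsPerCycle(protocol)
  c0 <- ringEccStart(protocol)
  lag <- as.integer(round((ecc - c0) / (protocol@ringMaxEcc - c0) * L))
  pmin(pmax(lag, 0L), L - 1L)
}

#' Bonferroni significance mask for retinotopy estimates
#'
#' Flags voxels whose peak-correlation p-value survives Bonferroni
#' correction: significant iff \code{p <= alpha / nTests}.  Because the
#' peak is selected over all lags, the default family is voxels x lags,
#' which by the union bound controls the family-wise error over the whole
#' selection and is therefore conservative; pass \code{nTests} equal to
#' the voxel count for a per-voxel-only correction.
#'
#' @param estimates data.frame from [crosscorrMap()].
#' @param alpha family-wise error level (default 0.05).
#' @param nTests size of the test family; defaults to
#'   \code{number of valid voxels * nLags}.
#' @return \code{estimates} with a logical \code{significant} column
#'   added.
#' @export
significanceMask <- function(estimates, alpha = 0.05, nTests = NULL) {
  if (is.null(nTests)) {
    nLags <- attr(estimates, "nLags")
    if (is.null(nLags)) nLags <- 100L
    nTests <- sum(estimates$valid) * nLags
  }
  estimates$significant <- estimates$valid &
    !is.na(estimates$p_value) & estimates$p_value <= alpha / nTests
  estimates
}
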