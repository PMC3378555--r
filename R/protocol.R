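#' Construct a mapping protocol
#'
#' Creates the timing/geometry description of a phase-encoded retinotopic
#' mapping run.  The defaults describe the standard session simulated by
#' this package: eight clockwise 54,000 ms cycles (wedge) or eight
#' expansion cycles (ring), volumes every 540 ms, 27,000 ms blanks at both
#' ends, a 45 degree wedge, a ring covering 0.4--7.5 degrees with width
#' 1/5 of the maximum radius, and 7,200 ms of assumed activation per cycle
#' at any one visual-field location.
#'
#' @param cycleMs,nCycles,volumeMs,blankMs,wedgeWidthDeg,ringMinEcc,ringMaxEcc,ringWidthFrac,onDurationMs,startAngleDeg
#'   see [MappingProtocol-class].
#' @return a validated [MappingProtocol-class] object.
#' @examples
#' p <- mappingProtocol()
#' lagsPerCycle(p)  # 100 volumes (and cross-correlation lags) per cycle
#' nVolumes(p)      # 900 volumes per run
#' @export
mappingProtocol <- function(cycleMs = 54000, nCycles = 8L, volumeMs = 540,
                            blankMs = 27000, wedgeWidthDeg = 45,
                            ringMinEcc = 0.4, ringMaxEcc = 7.5,
                            ringWidthFrac = 0.2, onDurationMs = 7200,
                            startAngleDeg = 0) {
  new("MappingProtocol", cycleMs = cycleMs, nCycles = as.integer(nCycles),
      volumeMs = volumeMs, blankMs = blankMs, wedgeWidthDeg = wedgeWidthDeg,
      ringMinEcc = ringMinEcc, ringMaxEcc = ringMaxEcc,
      ringWidthFrac = ringWidthFrac, onDurationMs = onDurationMs,
      startAngleDeg = startAngleDeg)
}

#' @rdname mappingProtocol
#' @param x a \code{MappingProtocol}.
#' @export
setMethod("lagsPerCycle", "MappingProtocol", function(x)
  as.integer(x@cycleMs / x@volumeMs))

#' @export
setMethod("nVolumes", "MappingProtocol", function(x)
  as.integer((x@nCycles * x@cycleMs + 2 * x@blankMs) / x@volumeMs))

#' @export
setMethod("volumeMs", "MappingProtocol", function(x) x@volumeMs)

# centre eccentricity represented by the start of the ring cycle: the ring's
# inner edge sits at ringMinEcc, so its centre is half a ring width further out
ringEccStart <- function(protocol)
  protocol@ringMinEcc + protocol@ringWidthFrac * protocol@ringMaxEcc / 2

setMethod("show", "MappingProtocol", function(object) {
  cat("MappingProtocol:", object@nCycles, "cycles of", object@cycleMs,
      "ms,", object@volumeMs, "ms volumes,", object@blankMs,
      "ms lead/trail blanks\n")
  cat("  wedge:", object@wedgeWidthDeg, "deg, start angle",
      object@startAngleDeg, "deg (clockwise)\n")
  cat("  ring:", object@ringMinEcc, "-", object@ringMaxEcc,
      "deg, width fraction", object@ringWidthFrac, "\n")
  cat("  ", lagsPerCycle(object), " volumes/cycle, ", nVolumes(object),
      " volumes/run\n", sep = "")
})

#' Construct a ground-truth effect specification
#'
#' @param ampS1,ampS2 transient stimulus response amplitudes.
#' @param delayMatchAmp,delayMismatchAmp sustained delay-period amplitudes
#'   added to the matching / mismatching region; scalar, or a named vector
#'   with entries for V1, V2, V3 to inject area-specific effects.
#' @param eccAmp amplitude of the eccentricity-modulated stimulus response.
#' @param ar1Rho lag-1 autocorrelation of the voxel noise.
#' @param driftCoeffs length-2 amplitudes (linear, half-cosine) of the
#'   low-frequency drift.
#' @param mappingAmp response amplitude during mapping runs.
#' @return a validated [EffectSpec-class] object.
#' @examples
#' effectSpec(delayMatchAmp = c(V1 = 0, V2 = 0, V3 = 0.3))
#' @export
effectSpec <- function(ampS1 = 1.5, ampS2 = 1.5, delayMatchAmp = 0,
                       delayMismatchAmp = 0, eccAmp = 0, ar1Rho = 0.3,
                       driftCoeffs = c(0, 0), mappingAmp = 3) {
  new("EffectSpec", ampS1 = ampS1, ampS2 = ampS2,
      delayMatchAmp = delayMatchAmp, delayMismatchAmp = delayMismatchAmp,
      eccAmp = eccAmp, ar1Rho = ar1Rho, driftCoeffs = driftCoeffs,
      mappingAmp = mappingAmp)
}

# resolve a scalar-or-named amplitude for one area
areaAmp <- function(amp, area) {
  if (is.null(names(amp))) return(amp[[1L]])
  if (!area %in% names(amp))
    stop("no amplitude entry for area ", area)
  unname(amp[[area]])
}

setMethod("show", "EffectSpec", function(object) {
  fmtAmp <- function(a) if (is.null(names(a))) format(a) else
    paste(names(a), format(a), sep = "=", collapse = " ")
  cat("EffectSpec: ampS1", object@ampS1, "ampS2", object@ampS2,
      "eccAmp", object@eccAmp, "\n")
  cat("  delayMatchAmp:", fmtAmp(object@delayMatchAmp),
      " delayMismatchAmp:", fmtAmp(object@delayMismatchAmp), "\n")
  cat("  noise: ar1Rho", object@ar1Rho, "drift",
      paste(object@driftCoeffs, collapse = "/"),
      " mappingAmp", object@mappingAmp, "\n")
})

#' Construct a BoldSeries container
#'
#' @param data voxel x volume numeric matrix of BOLD signal.
#' @param volumeMs volume interval in ms.
#' @param sheet optional [VoxelSheet-class]; its voxel table becomes the
#'   rowData of the container.
#' @param sessionType free-form label (\code{"mapping"}, \code{"task"}).
#' @param stimulus for mapping runs, \code{"wedge"} or \code{"ring"}.
#' @param extra named list merged into the metadata.
#' @return a [BoldSeries-class] object.
#' @export
boldSeries <- function(data, volumeMs, sheet = NULL,
                       sessionType = NA_character_,
                       stimulus = NA_character_, extra = list()) {
  rd <- if (!is.null(sheet)) voxelData(sheet) else
    S4Vectors::DataFrame(voxel_id = seq_len(nrow(data)))
  se <- SummarizedExperiment(
    assays = list(bold = data), rowData = rd,
    metadata = c(list(volumeMs = volumeMs, sessionType = sessionType,
                      stimulus = stimulus), extra))
  new("BoldSeries", se)
}

#' @export
setMethod("volumeMs", "BoldSeries", function(x) metadata(x)$volumeMs)

#' @export
setMethod("nVolumes", "BoldSeries", function(x) ncol(x))

setMethod("show", "BoldSeries", function(object) {
  cat("BoldSeries:", nrow(object), "voxels x", ncol(object), "volumes,",
      volumeMs(object), "ms/volume")
  st <- metadata(object)$sessionType
  if (!is.na(st)) cat(" [", st, sep = "")
  stim <- metadata(object)$stimulus
  if (!is.na(stim)) cat("/", stim, sep = "")
  if (!is.na(st)) cat("]")
  cat("\n")
})
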