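#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

#' Timing and geometry of a phase-encoded mapping run
#'
#' Describes one retinotopic mapping session: a stimulus (rotating wedge or
#' expanding ring) traverses the visual field periodically while volumes are
#' acquired on a fixed grid.  Defaults correspond to eight 54,000 ms cycles
#' sampled every 540 ms, with 27,000 ms fixation-only blanks at the start and
#' end of the series, a 45 degree wedge, and a ring spanning 0.4--7.5 degrees
#' of eccentricity with a width of 1/5 of the maximum stimulus radius.
#'
#' @slot cycleMs duration of one stimulus cycle in ms.
#' @slot nCycles number of cycles per run.
#' @slot volumeMs volume acquisition interval in ms.
#' @slot blankMs duration of the fixation-only blank at each end of the run.
#' @slot wedgeWidthDeg angular width of the wedge in degrees.
#' @slot ringMinEcc,ringMaxEcc inner and outer eccentricity limits (degrees
#'   of visual angle) of the ring's traversal.
#' @slot ringWidthFrac ring width as a fraction of \code{ringMaxEcc}.
#' @slot onDurationMs per-cycle activation duration (ms) assumed for any one
#'   visual-field location; this is the on-duration of the cyclic regressor.
#' @slot startAngleDeg polar angle (degrees, 0 = upper vertical meridian,
#'   increasing clockwise) at which the wedge's leading edge sits at cycle
#'   onset.
#'
#' @seealso [mappingProtocol()]
#' @export
setClass("MappingProtocol",
  representation(
    cycleMs = "numeric", nCycles = "integer", volumeMs = "numeric",
    blankMs = "numeric", wedgeWidthDeg = "numeric",
    ringMinEcc = "numeric", ringMaxEcc = "numeric",
    ringWidthFrac = "numeric", onDurationMs = "numeric",
    startAngleDeg = "numeric"))

setValidity("MappingProtocol", function(object) {
  msg <- character()
  if (object@cycleMs %% object@volumeMs != 0)
    msg <- c(msg, "cycleMs must be divisible by volumeMs")
  if (object@blankMs %% object@volumeMs != 0)
    msg <- c(msg, "blankMs must be divisible by volumeMs")
  if (object@onDurationMs >= object@cycleMs)
    msg <- c(msg, "onDurationMs must be smaller than cycleMs")
  if (object@ringMinEcc >= object@ringMaxEcc)
    msg <- c(msg, "ringMinEcc must be smaller than ringMaxEcc")
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground-truth effect amplitudes and noise model for the simulator
#'
#' Collects every knob of the synthetic BOLD generator: transient response
#' amplitudes for the two stimuli, sustained delay-period amplitudes for the
#' matching and mismatching visual-field regions (scalars, or named vectors
#' keyed by area to inject area-specific effects such as a V3-only
#' modulation), an eccentricity-modulation amplitude, the AR(1) coefficient
#' and drift amplitudes of the noise model, and the amplitude of the
#' mapping-run response.  All amplitudes are in the arbitrary signal units of
#' the simulator (think percent signal change around a zero baseline).
#'
#' @slot ampS1,ampS2 transient response amplitude to the first and second
#'   stimulus of a trial.
#' @slot delayMatchAmp,delayMismatchAmp sustained amplitude added during
#'   each retention interval to voxels of the matching (resp. mismatching)
#'   region; scalar or named per-area vector (names in V1/V2/V3).
#' @slot eccAmp amplitude of the eccentricity-modulated stimulus response
#'   (per degree of mean-centred stimulus eccentricity).
#' @slot ar1Rho lag-1 autocorrelation of the voxel noise, in [0, 1).
#' @slot driftCoeffs length-2 numeric: amplitudes of a linear and a
#'   half-cosine low-frequency drift spanning the run.
#' @slot mappingAmp response amplitude of the mapping-run boxcar.
#'
#' @seealso [effectSpec()]
#' @export
setClass("EffectSpec",
  representation(
    ampS1 = "numeric", ampS2 = "numeric",
    delayMatchAmp = "numeric", delayMismatchAmp = "numeric",
    eccAmp = "numeric", ar1Rho = "numeric", driftCoeffs = "numeric",
    mappingAmp = "numeric"))

setValidity("EffectSpec", function(object) {
  msg <- character()
  amps <- c(object@ampS1, object@ampS2, object@delayMatchAmp,
            object@delayMismatchAmp, object@eccAmp, object@mappingAmp)
  if (!all(is.finite(amps))) msg <- c(msg, "all amplitudes must be finite")
  if (object@ar1Rho < 0 || object@ar1Rho >= 1)
    msg <- c(msg, "ar1Rho must lie in [0, 1)")
  if (length(object@driftCoeffs) != 2L)
    msg <- c(msg, "driftCoeffs must have length 2 (linear, cosine)")
  if (length(msg)) msg else TRUE
})

#' Hemodynamic response kernel sampled on a volume grid
#'
#' @slot samples kernel values at \code{samplingMs} spacing, starting at
#'   t = 0; peak-normalised to 1.
#' @slot samplingMs sampling interval in ms.
#'
#' @seealso [canonicalHrf()]
#' @export
setClass("HrfKernel",
  representation(samples = "numeric", samplingMs = "numeric"))

setValidity("HrfKernel", function(object) {
  msg <- character()
  if (length(object@samples) * object@samplingMs < 30000)
    msg <- c(msg, "kernel must cover at least 30 s")
  s <- sum(object@samples) * object@samplingMs
  if (!is.finite(s) || s <= 0)
    msg <- c(msg, "kernel must integrate to a finite positive value")
  if (length(msg)) msg else TRUE
})

#' Simulated sheet of retinotopically organised voxels
#'
#' Each simulated voxel carries a ground-truth visual area label (V1, V2 or
#' V3), the polar angle and eccentricity of its receptive field, the quadrant
#' and eccentricity-ring cell it was generated in, a response gain, and its
#' noise standard deviation.
#'
#' @slot voxels a [S4Vectors::DataFrame] with columns \code{voxel_id},
#'   \code{area}, \code{quadrant}, \code{ring}, \code{polar_deg},
#'   \code{ecc_deg}, \code{gain}, \code{noise_sd}.
#' @slot maxEcc maximum eccentricity of the generating protocol (degrees).
#'
#' @seealso [generateVoxelSheet()]
#' @export
setClass("VoxelSheet",
  representation(voxels = "DataFrame", maxEcc = "numeric"))

setValidity("VoxelSheet", function(object) {
  v <- object@voxels
  need <- c("voxel_id", "area", "quadrant", "ring", "polar_deg", "ecc_deg",
            "gain", "noise_sd")
  msg <- character()
  if (!all(need %in% colnames(v)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, colnames(v)), collapse = ", ")))
  else {
    if (any(v$polar_deg < 0 | v$polar_deg >= 360))
      msg <- c(msg, "polar_deg must lie in [0, 360)")
    if (any(v$ecc_deg <= 0 | v$ecc_deg > object@maxEcc))
      msg <- c(msg, "ecc_deg must lie in (0, maxEcc]")
    if (!all(v$area %in% c("V1", "V2", "V3")))
      msg <- c(msg, "area labels must be V1, V2 or V3")
    if (any(v$gain < 0) || any(v$noise_sd < 0))
      msg <- c(msg, "gain and noise_sd must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Container for simulated or observed BOLD time series
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment]: the
#' \code{"bold"} assay holds a voxel x volume signal matrix, \code{rowData}
#' carries the voxel sheet metadata, and \code{metadata} records the volume
#' interval (\code{volumeMs}), the session type and, for mapping runs, the
#' stimulus (\code{"wedge"} or \code{"ring"}).
#'
#' @seealso [boldSeries()], [simulateMappingSeries()], [simulateTaskSeries()]
#' @export
setClass("BoldSeries", contains = "SummarizedExperiment")

setValidity("BoldSeries", function(object) {
  msg <- character()
  if (!"bold" %in% assayNames(object))
    msg <- c(msg, "assay 'bold' is required")
  else if (anyNA(assay(object, "bold")))
    msg <- c(msg, "bold assay must not contain missing values")
  if (is.null(metadata(object)$volumeMs))
    msg <- c(msg, "metadata volumeMs is required")
  if (length(msg)) msg else TRUE
})

#' Assignment of voxels to the four visual-field segments
#'
#' Either the four polar-angle quadrants (\code{mode = "quadrant"}) or the
#' four eccentricity rings (\code{mode = "ring"}).  Only voxels that passed
#' the retinotopy significance mask are assigned.
#'
#' @slot mode \code{"quadrant"} or \code{"ring"}.
#' @slot assignment [S4Vectors::DataFrame] with columns \code{voxel_id},
#'   \code{area}, \code{segment} (integer 1..4).
#'
#' @seealso [assignPolarSegments()], [assignEccSegments()]
#' @export
setClass("SegmentMap",
  representation(mode = "character", assignment = "DataFrame"))

setValidity("SegmentMap", function(object) {
  msg <- character()
  if (!object@mode %in% c("quadrant", "ring"))
    msg <- c(msg, "mode must be 'quadrant' or 'ring'")
  a <- object@assignment
  if (!all(c("voxel_id", "area", "segment") %in% colnames(a)))
    msg <- c(msg, "assignment needs columns voxel_id, area, segment")
  else if (nrow(a) && !all(a$segment %in% 1:4))
    msg <- c(msg, "segment indices must lie in 1..4")
  if (length(msg)) msg else TRUE
})

#' Mean time courses of the four segments of one visual area
#'
#' Holds the per-volume mean BOLD series of each of the four visual-field
#' segments of one area, in fixed segment order 1..4.  The concatenation of
#' the four series (length 4 T) is the response vector of the
#' concatenated-segment GLM.
#'
#' @slot area area label (V1, V2, V3).
#' @slot mode segmentation mode (\code{"quadrant"} or \code{"ring"}).
#' @slot segMeans T x 4 matrix of segment mean series.
#' @slot volumeMs volume interval in ms.
#'
#' @seealso [extractSegmentTimecourses()], [concatTimecourse()]
#' @export
setClass("SegmentTimecourses",
  representation(area = "character", mode = "character",
                 segMeans = "matrix", volumeMs = "numeric"))

setValidity("SegmentTimecourses", function(object) {
  msg <- character()
  if (ncol(object@segMeans) != 4L)
    msg <- c(msg, "segMeans must have exactly 4 columns")
  if (anyNA(object@segMeans))
    msg <- c(msg, "segMeans must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Design matrix for the concatenated-segment GLM
#'
#' The design spans the concatenation of the four segment time courses
#' (4 T rows).  Neural columns (delay-match, delay-mismatch, stimulus events,
#' eccentricity modulator, or per-segment stimulus columns) are
#' HRF-convolved within their segment block only; each block additionally
#' receives its own constant and discrete-cosine high-pass columns so that
#' concatenation does not couple baselines.
#'
#' @slot design numeric matrix, 4 T x p, with named columns.
#' @slot blockIndex integer vector of length 4 T giving the segment block
#'   (1..4) of each row.
#' @slot neuralColumns names of the effect-carrying columns.
#' @slot mode segmentation mode the design was built under.
#' @slot volumeMs volume interval in ms.
#'
#' @seealso [buildConcatenatedDesign()], [fitGlm()]
#' @export
setClass("ConcatDesign",
  representation(design = "matrix", blockIndex = "integer",
                 neuralColumns = "character", mode = "character",
                 volumeMs = "numeric"))

setValidity("ConcatDesign", function(object) {
  msg <- character()
  if (nrow(object@design) != length(object@blockIndex))
    msg <- c(msg, "blockIndex length must equal nrow(design)")
  if (!all(object@neuralColumns %in% colnames(object@design)))
    msg <- c(msg, "neuralColumns must name columns of the design")
  if (length(msg)) msg else TRUE
})
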