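#' Generate a retinotopically organised voxel sheet
#'
#' Simulates \code{nPerArea} voxels for each of V1, V2 and V3 whose
#' receptive fields tile the visual field: every combination of the four
#' polar-angle quadrants (Q1 = 0--90 degrees at the upper right, proceeding
#' clockwise from the upper vertical meridian) and the four eccentricity
#' rings centred on the stimulus radii 1.875, 3.75, 5.625 and 7.5 degrees is
#' populated.  Within a cell, polar angles are drawn uniformly inside the
#' quadrant with a safety margin from the quadrant borders, and
#' eccentricities uniformly around the ring radius but inside the ring's
#' decoding boundaries (midpoints between adjacent radii), so that the
#' ground-truth labels are recoverable by noiseless phase mapping.
#'
#' @param nPerArea voxels per area, at least 16 (one per quadrant x ring
#'   cell).
#' @param protocol a [MappingProtocol-class]; bounds the eccentricity range.
#' @param seed integer seed; the sheet is deterministic given the seed.
#' @param gain,noiseSd per-voxel response gain and noise SD (recycled).
#' @param polarMarginDeg margin kept from quadrant borders (degrees).
#' @param eccJitter half-width of the uniform eccentricity jitter around
#'   each ring radius (degrees).
#' @return a [VoxelSheet-class] with \code{3 * nPerArea} voxels.
#' @examples
#' sheet <- generateVoxelSheet(32, mappingProtocol(), seed = 1)
#' nVoxels(sheet)
#' @export
generateVoxelSheet <- function(nPerArea, protocol = mappingProtocol(),
                               seed = 1L, gain = 1, noiseSd = 1,
                               polarMarginDeg = 6, eccJitter = 0.35) {
  if (nPerArea < 16)
    stop("nPerArea must be at least 16 so every quadrant x ring cell of ",
         "each area is occupied")
  withr::local_seed(seed)
  radii <- stimulusRadii(protocol)
  mids <- (radii[-length(radii)] + radii[-1]) / 2
  lo <- c(max(ringEccStart(protocol) + 0.1, radii[1] - 1), mids)
  hi <- c(mids, protocol@ringMaxEcc)
  eccMargin <- 0.07  # keep > one lag bin away from decoding boundaries
  areas <- c("V1", "V2", "V3")
  cells <- expand.grid(quadrant = 1:4, ring = 1:4)
  base <- nPerArea %/% 16L
  extra <- nPerArea %% 16L
  cellCounts <- rep(base, 16L) + as.integer(seq_len(16L) <= extra)
  out <- do.call(rbind, lapply(areas, function(a) {
    q <- rep(cells$quadrant, cellCounts)
    r <- rep(cells$ring, cellCounts)
    polar <- stats::runif(length(q), 90 * (q - 1) + polarMarginDeg,
                          90 * q - polarMarginDeg)
    ecc <- stats::runif(length(r), pmax(radii[r] - eccJitter, lo[r] + eccMargin),
                        pmin(radii[r] + eccJitter, hi[r] - eccMargin))
    data.frame(area = a, quadrant = q, ring = r, polar_deg = polar,
               ecc_deg = ecc)
  }))
  n <- nrow(out)
  vox <- S4Vectors::DataFrame(
    voxel_id = seq_len(n), area = out$area, quadrant = out$quadrant,
    ring = out$ring, polar_deg = out$polar_deg, ecc_deg = out$ecc_deg,
    gain = rep_len(gain, n), noise_sd = rep_len(noiseSd, n))
  new("VoxelSheet", voxels = vox, maxEcc = protocol@ringMaxEcc)
}

# the four analysis radii of the dot stimuli: quarters of the maximum
# stimulus eccentricity
stimulusRadii <- function(protocol = mappingProtocol())
  protocol@ringMaxEcc * (1:4) / 4

#' @rdname generateVoxelSheet
#' @param x a \code{VoxelSheet}.
#' @export
setMethod("voxelData", "VoxelSheet", function(x) x@voxels)

#' @export
setMethod("nVoxels", "VoxelSheet", function(x) nrow(x@voxels))

setMethod("show", "VoxelSheet", function(object) {
  v <- object@voxels
  cat("VoxelSheet:", nrow(v), "voxels,",
      paste(unique(v$area), collapse = "/"),
      "- max eccentricity", object@maxEcc, "deg\n")
  print(table(area = v$area, ring = v$ring))
})
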