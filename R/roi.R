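#' Bin phase estimates into the four visual-field segments
#'
#' \code{assignPolarSegments} interpolates decoded polar angles to four
#' steps -- the quadrants 0--90, 90--180, 180--270 and 270--360 degrees --
#' using half-open bins \code{[lo, hi)} (a voxel exactly on a boundary
#' belongs to the upper quadrant; 360 wraps to quadrant 1).
#' \code{assignEccSegments} bins decoded eccentricities into four rings
#' centred on the stimulus radii, with boundaries at the midpoints between
#' adjacent radii; a voxel exactly on a midpoint joins the lower ring, and
#' eccentricities below the lowest or above the highest radius clamp to
#' rings 1 and 4.  Only voxels flagged significant (or valid, when no
#' significance mask has been applied) are assigned.
#'
#' @param estimates data.frame from [crosscorrMap()], optionally passed
#'   through [significanceMask()].
#' @param boundaries polar bin edges in degrees (quadrant mode).
#' @param radii ring-centre radii in degrees (ring mode).
#' @return a [SegmentMap-class].
#' @examples
#' est <- data.frame(voxel_id = 1:3, area = "V1",
#'                   polar_deg = c(45, 90, 359), valid = TRUE)
#' segmentAssignment(assignPolarSegments(est))$segment  # 1 2 4
#' @export
assignPolarSegments <- function(estimates,
                                boundaries = c(0, 90, 180, 270, 360)) {
  stopifnot("polar_deg" %in% names(estimates))
  keep <- segmentEligible(estimates)
  polar <- estimates$polar_deg[keep] %% 360
  seg <- findInterval(polar, boundaries, rightmost.closed = FALSE)
  newSegmentMap("quadrant", estimates, keep, seg)
}

#' @rdname assignPolarSegments
#' @export
assignEccSegments <- function(estimates,
                              radii = c(1.875, 3.75, 5.625, 7.5)) {
  stopifnot("ecc_deg" %in% names(estimates))
  keep <- segmentEligible(estimates)
  mids <- (radii[-length(radii)] + radii[-1]) / 2
  # left-open intervals: a voxel exactly on a midpoint joins the lower ring
  seg <- findInterval(estimates$ecc_deg[keep], mids, left.open = TRUE) + 1L
  newSegmentMap("ring", estimates, keep, seg)
}

segmentEligible <- function(estimates) {
  if ("significant" %in% names(estimates)) estimates$significant
  else if ("valid" %in% names(estimates)) estimates$valid
  else rep(TRUE, nrow(estimates))
}

newSegmentMap <- function(mode, estimates, keep, seg) {
  new("SegmentMap", mode = mode, assignment = S4Vectors::DataFrame(
    voxel_id = estimates$voxel_id[keep],
    area = if ("area" %in% names(estimates)) estimates$area[keep]
           else rep(NA_character_, sum(keep)),
    segment = as.integer(seg)))
}

#' @rdname assignPolarSegments
#' @param x a \code{SegmentMap}.
#' @export
setMethod("segmentMode", "SegmentMap", function(x) x@mode)

#' @export
setMethod("segmentAssignment", "SegmentMap", function(x) x@assignment)

setMethod("show", "SegmentMap", function(object) {
  cat("SegmentMap (", object@mode, "): ", nrow(object@assignment),
      " voxels assigned\n", sep = "")
  print(table(segment = object@assignment$segment))
})

#' Resolve the matching and mismatching regions of each trial
#'
#' Under the categorical instruction a second stimulus matches when it
#' appears in the quadrant diagonally opposite the first stimulus, so the
#' matching region is the opposite quadrant; the mismatching region
#' comprises the two remaining quadrants -- the quadrant of the first
#' stimulus itself is excluded by default so that residual S1 activation
#' (carried by the S1 factor) is not confounded with delay-period
#' mismatch activity (set \code{excludeS1Quadrant = FALSE} to include
#' it).  Under the coordinate instruction the matching region is the ring
#' at the first stimulus' radial distance, across all quadrants, and the
#' mismatching region the other three rings.  Catch trials resolve their
#' regions from S1 alone.
#'
#' @param trials trial table from [generateTrialSequence()].
#' @param excludeS1Quadrant drop S1's own quadrant from the categorical
#'   mismatching region (default TRUE).
#' @return data.frame with one row per trial: \code{trial_id},
#'   \code{mode}, \code{s1_segment}, \code{s2_segment} (NA for catch),
#'   \code{matching_segment} and the list column
#'   \code{mismatching_segments}.
#' @export
resolveRegions <- function(trials, excludeS1Quadrant = TRUE) {
  if (!nrow(trials)) {
    out <- data.frame(trial_id = integer(), mode = character(),
                      s1_segment = integer(), s2_segment = integer(),
                      matching_segment = integer())
    out$mismatching_segments <- list()
    return(out)
  }
  instruction <- trials$instruction[1]
  if (instruction == "categorical") {
    s1seg <- trials$s1_quadrant
    s2seg <- trials$s2_quadrant
    matching <- oppositeQuadrant(s1seg)
    mism <- lapply(seq_along(s1seg), function(i)
      setdiff(1:4, if (excludeS1Quadrant) c(matching[i], s1seg[i])
              else matching[i]))
    mode <- "quadrant"
  } else if (instruction == "coordinate") {
    s1seg <- trials$s1_ring
    s2seg <- trials$s2_ring
    matching <- s1seg
    mism <- lapply(matching, function(m) setdiff(1:4, m))
    mode <- "ring"
  } else stop("unknown instruction: ", instruction)
  out <- data.frame(trial_id = trials$trial_id, mode = mode,
                    s1_segment = s1seg, s2_segment = s2seg,
                    matching_segment = as.integer(matching))
  out$mismatching_segments <- mism
  out
}
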