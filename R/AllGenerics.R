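#' @rdname boldSeries
#' @param x,object an object.
#' @export
setGeneric("volumeMs", function(x) standardGeneric("volumeMs"))

#' @rdname generateVoxelSheet
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname generateVoxelSheet
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Number of volumes implied by a protocol or carried by a series
#'
#' For a [MappingProtocol-class] this is
#' (nCycles * cycleMs + 2 * blankMs) / volumeMs; for a [BoldSeries-class]
#' it is the number of acquired volumes (columns of the bold assay).
#'
#' @param x a \code{MappingProtocol} or \code{BoldSeries}.
#' @return integer volume count.
#' @examples
#' nVolumes(mappingProtocol())  # 900
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname mappingProtocol
#' @export
setGeneric("lagsPerCycle", function(x) standardGeneric("lagsPerCycle"))

#' @rdname assignPolarSegments
#' @export
setGeneric("segmentMode", function(x) standardGeneric("segmentMode"))

#' @rdname assignPolarSegments
#' @export
setGeneric("segmentAssignment", function(x) standardGeneric("segmentAssignment"))

#' Concatenated segment time course
#'
#' Returns the four segment mean series of a [SegmentTimecourses-class]
#' stacked in fixed segment order 1..4, a vector of length 4 T.
#'
#' @param x a \code{SegmentTimecourses} object.
#' @return numeric vector of length 4 T.
#' @export
setGeneric("concatTimecourse", function(x) standardGeneric("concatTimecourse"))

#' @rdname buildConcatenatedDesign
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
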