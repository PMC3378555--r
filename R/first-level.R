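#' Extract and concatenate segment mean time courses
#'
#' Averages, volume by volume, the signal of all voxels assigned to each of
#' the four visual-field segments of one area, yielding the four mean
#' series whose concatenation (fixed segment order 1..4, length 4 T) is the
#' response vector of the concatenated-segment GLM.
#'
#' @param series a [BoldSeries-class] task session.
#' @param segmap a [SegmentMap-class].
#' @param area which visual area to extract (V1, V2 or V3).
#' @return a [SegmentTimecourses-class].
#' @export
extractSegmentTimecourses <- function(series, segmap, area) {
  a <- segmentAssignment(segmap)
  a <- a[a$area == area, ]
  X <- assay(series, "bold")
  ids <- rowData(series)$voxel_id
  segMeans <- vapply(1:4, function(s) {
    vox <- a$voxel_id[a$segment == s]
    if (!length(vox))
      stop("segment ", s, " of area ", area, " (", segmentMode(segmap),
           " mode) contains no voxels")
    colMeans(X[match(vox, ids), , drop = FALSE])
  }, numeric(ncol(X)))
  new("SegmentTimecourses", area = area, mode = segmentMode(segmap),
      segMeans = segMeans, volumeMs = volumeMs(series))
}

#' @export
setMethod("concatTimecourse", "SegmentTimecourses", function(x)
  as.vector(x@segMeans))

#' @export
setMethod("volumeMs", "SegmentTimecourses", function(x) x@volumeMs)

#' @export
setMethod("nVolumes", "SegmentTimecourses", function(x) nrow(x@segMeans))

setMethod("show", "SegmentTimecourses", function(object) {
  cat("SegmentTimecourses: area", object@area, "(", object@mode,
      "mode ),", nrow(object@segMeans), "volumes/segment,",
      "concatenated length", 4 * nrow(object@segMeans), "\n")
})

# per-block constant and DCT high-pass columns of the concatenated design
concatNuisance <- function(nVol, nDct) {
  D <- dctBasis(nVol, nDct)
  out <- matrix(0, 4 * nVol, 4 * (1 + nDct))
  cn <- character(ncol(out))
  for (b in 1:4) {
    rows <- (b - 1) * nVol + seq_len(nVol)
    j0 <- (b - 1) * (1 + nDct)
    out[rows, j0 + 1] <- 1
    out[rows, j0 + 1 + seq_len(nDct)] <- D
    cn[j0 + 1] <- paste0("const_b", b)
    cn[j0 + 1 + seq_len(nDct)] <- paste0("b", b, "_dct", seq_len(nDct))
  }
  colnames(out) <- cn
  out
}

# stack per-block pieces (list of 4 length-T vectors) into a 4T column
stackBlocks <- function(pieces) unlist(pieces, use.names = FALSE)

checkTrialOverlap <- function(trials) {
  dw <- delayWindow(trials)
  o <- order(trials$s1_onset_ms)
  tt <- trialTiming()
  spanEnd <- pmax(dw$end_ms[o] + tt$stimMs + tt$respMs,
                  dw$end_ms[o])[-nrow(trials)]
  nextStart <- trials$s1_onset_ms[o][-1]
  if (any(spanEnd > nextStart))
    stop("overlapping trials: trial spans must not intersect")
}

# segment of each stimulus under a segmentation mode
stimulusSegment <- function(trials, mode, which = c("s1", "s2")) {
  which <- match.arg(which)
  if (mode == "quadrant") trials[[paste0(which, "_quadrant")]]
  else trials[[paste0(which, "_ring")]]
}

#' Build the concatenated five-factor delay design
#'
#' Constructs the design matrix of the concatenated-segment GLM over the
#' stacked segment time courses (4 T rows).  Five neural factors are
#' modelled, each placed in the segment blocks where the corresponding
#' activation is expected and HRF-convolved within its block:
#' \code{delay_match} and \code{delay_mismatch} are retention-interval
#' boxcars (S1 offset to S2 onset) placed in each trial's matching
#' (resp. mismatching) segment blocks; \code{s1} and \code{s2} are single
#' events placed in the block of the segment containing the stimulus;
#' \code{ecc_mod} carries the same events weighted by mean-centred
#' stimulus eccentricity, absorbing cortical-magnification differences in
#' response amplitude.  Each block additionally receives its own constant
#' and DCT high-pass columns.  All-zero neural columns (e.g. with an empty
#' trial list) are dropped.
#'
#' @param trials trial table from [generateTrialSequence()].
#' @param regions region table from [resolveRegions()].
#' @param nVolumes volumes per segment series (T).
#' @param volumeMs volume interval in ms.
#' @param hrf optional [HrfKernel-class] at \code{volumeMs}.
#' @param nDct DCT columns per block (default 8).
#' @return a [ConcatDesign-class].
#' @export
buildConcatenatedDesign <- function(trials, regions, nVolumes, volumeMs,
                                    hrf = NULL, nDct = 8L) {
  if (is.null(hrf)) hrf <- canonicalHrf(volumeMs)
  if (nrow(trials)) checkTrialOverlap(trials)
  mode <- if (nrow(trials)) regions$mode[1] else "quadrant"
  dw <- delayWindow(trials)
  rbar <- eventRadiusMean(trials)
  s1seg <- stimulusSegment(trials, mode, "s1")
  s2seg <- stimulusSegment(trials, mode, "s2")
  noS2 <- is.na(trials$s2_onset_ms)
  reg <- function(onsets, durations = 0, weights = 1)
    eventRegressor(onsets, durations, nVolumes, volumeMs, hrf,
                   weights = weights)
  cols <- lapply(1:4, function(s) {
    im <- which(regions$matching_segment == s)
    imm <- which(vapply(regions$mismatching_segments,
                        function(m) s %in% m, logical(1)))
    i1 <- which(s1seg == s)
    i2 <- which(!noS2 & s2seg == s)
    eccOn <- c(trials$s1_onset_ms[i1], trials$s2_onset_ms[i2])
    eccW <- c(trials$s1_radius[i1], trials$s2_radius[i2]) - rbar
    list(delay_match = reg(dw$start_ms[im], dw$end_ms[im] - dw$start_ms[im]),
         delay_mismatch = reg(dw$start_ms[imm],
                              dw$end_ms[imm] - dw$start_ms[imm]),
         s1 = reg(trials$s1_onset_ms[i1]),
         s2 = reg(trials$s2_onset_ms[i2]),
         ecc_mod = reg(eccOn, weights = eccW))
  })
  neural <- vapply(c("delay_match", "delay_mismatch", "s1", "s2", "ecc_mod"),
                   function(nm) stackBlocks(lapply(cols, `[[`, nm)),
                   numeric(4 * nVolumes))
  keep <- colSums(abs(neural)) > 0
  if (!all(keep))
    message("dropping all-zero design column(s): ",
            paste(colnames(neural)[!keep], collapse = ", "))
  X <- cbind(neural[, keep, drop = FALSE], concatNuisance(nVolumes, nDct))
  new("ConcatDesign", design = X,
      blockIndex = rep(1:4, each = nVolumes),
      neuralColumns = colnames(neural)[keep], mode = mode,
      volumeMs = volumeMs)
}

#' @rdname buildConcatenatedDesign
#' @param x a \code{ConcatDesign}.
#' @export
setMethod("designMatrix", "ConcatDesign", function(x) x@design)

setMethod("show", "ConcatDesign", function(object) {
  cat("ConcatDesign:", nrow(object@design), "rows x", ncol(object@design),
      "columns (", object@mode, "mode )\n")
  cat("  neural columns:", paste(object@neuralColumns, collapse = ", "),
      "\n")
})

# ordinary least squares with rank diagnostics
olsFit <- function(y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(y) != nrow(X))
    stop("length of the time course (", length(y),
         ") does not match the design (", nrow(X), " rows)")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  dfRes <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / dfRes
  XtXinv <- chol2inv(qr.R(qrX)[, order(qrX$pivot), drop = FALSE])
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  names(se) <- names(beta)
  list(beta = beta, se = se, sigma = sqrt(sigma2), dfResidual = dfRes,
       qr = qrX)
}

#' Fit the concatenated-segment GLM
#'
#' Ordinary least squares of the concatenated segment time course on the
#' concatenated design.  Coefficients are in signal units; residual
#' variance and degrees of freedom are attached as attributes.
#'
#' @param tcs a [SegmentTimecourses-class].
#' @param design a [ConcatDesign-class] built for the same session and
#'   mode.
#' @return data.frame with one row per neural factor: \code{factor},
#'   \code{beta}, \code{se}; attributes \code{sigma}, \code{dfResidual}
#'   and \code{allCoefficients}.
#' @export
fitGlm <- function(tcs, design) {
  stopifnot(is(tcs, "SegmentTimecourses"), is(design, "ConcatDesign"))
  if (tcs@mode != design@mode)
    stop("time courses (", tcs@mode, ") and design (", design@mode,
         ") use different segmentation modes")
  fit <- olsFit(concatTimecourse(tcs), designMatrix(design))
  nc <- design@neuralColumns
  out <- data.frame(factor = nc, beta = unname(fit$beta[nc]),
                    se = unname(fit$se[nc]), row.names = NULL)
  attr(out, "sigma") <- fit$sigma
  attr(out, "dfResidual") <- fit$dfResidual
  attr(out, "allCoefficients") <- fit$beta
  out
}

#' Stimulus-response betas with the second stimulus split by region
#'
#' Variant of the concatenated design in which the S2 events are split
#' into two factors according to whether the second stimulus fell in the
#' trial's matching region (\code{s2_match}; by the task's construction
#' these are the match trials) or not (\code{s2_mismatch}).  Delay and
#' eccentricity factors are retained as covariates.  A degenerate session
#' in which one of the S2 factors has no events drops that column with a
#' warning.
#'
#' @inheritParams buildConcatenatedDesign
#' @param tcs a [SegmentTimecourses-class] for the session.
#' @return data.frame of betas for \code{s1}, \code{s2_match} and
#'   \code{s2_mismatch} (present columns only), as in [fitGlm()].
#' @export
stimulusBetas <- function(tcs, trials, regions, hrf = NULL, nDct = 8L) {
  volumeMs <- tcs@volumeMs
  nVol <- nVolumes(tcs)
  if (is.null(hrf)) hrf <- canonicalHrf(volumeMs)
  checkTrialOverlap(trials)
  mode <- regions$mode[1]
  if (tcs@mode != mode)
    stop("time courses were extracted under a different segmentation mode")
  dw <- delayWindow(trials)
  rbar <- eventRadiusMean(trials)
  s1seg <- stimulusSegment(trials, mode, "s1")
  s2seg <- stimulusSegment(trials, mode, "s2")
  noS2 <- is.na(trials$s2_onset_ms)
  s2match <- !noS2 & regions$s2_segment == regions$matching_segment
  reg <- function(onsets, durations = 0, weights = 1)
    eventRegressor(onsets, durations, nVol, volumeMs, hrf, weights = weights)
  cols <- lapply(1:4, function(s) {
    im <- which(regions$matching_segment == s)
    imm <- which(vapply(regions$mismatching_segments,
                        function(m) s %in% m, logical(1)))
    i1 <- which(s1seg == s)
    i2m <- which(s2match & s2seg == s)
    i2n <- which(!noS2 & !s2match & s2seg == s)
    eccOn <- c(trials$s1_onset_ms[i1], trials$s2_onset_ms[c(i2m, i2n)])
    eccW <- c(trials$s1_radius[i1], trials$s2_radius[c(i2m, i2n)]) - rbar
    list(delay_match = reg(dw$start_ms[im], dw$end_ms[im] - dw$start_ms[im]),
         delay_mismatch = reg(dw$start_ms[imm],
                              dw$end_ms[imm] - dw$start_ms[imm]),
         s1 = reg(trials$s1_onset_ms[i1]),
         s2_match = reg(trials$s2_onset_ms[i2m]),
         s2_mismatch = reg(trials$s2_onset_ms[i2n]),
         ecc_mod = reg(eccOn, weights = eccW))
  })
  nms <- c("delay_match", "delay_mismatch", "s1", "s2_match", "s2_mismatch",
           "ecc_mod")
  neural <- vapply(nms, function(nm) stackBlocks(lapply(cols, `[[`, nm)),
                   numeric(4 * nVol))
  keep <- colSums(abs(neural)) > 0
  if (!all(keep))
    warning("degenerate session: dropping empty stimulus factor(s): ",
            paste(colnames(neural)[!keep], collapse = ", "))
  design <- new("ConcatDesign",
                design = cbind(neural[, keep, drop = FALSE],
                               concatNuisance(nVol, nDct)),
                blockIndex = rep(1:4, each = nVol),
                neuralColumns = colnames(neural)[keep], mode = mode,
                volumeMs = volumeMs)
  fit <- fitGlm(tcs, design)
  fit[fit$factor %in% c("s1", "s2_match", "s2_mismatch"), , drop = FALSE]
}

#' Contrast activation: stimulated versus non-stimulated segments
#'
#' Reliability measure for the segment definitions: for the stimuli of a
#' session, the difference between the response estimated in the segment
#' where a stimulus was presented and the mean response estimated in the
#' three segments where it was not.  Stimulus events (S1 and S2 pooled)
#' are grouped by the segment containing them under the requested
#' segmentation mode; each group is modelled in every segment block
#' (16 columns), and the contrast of group j is
#' \code{beta[j, j] - mean(beta[j, k != j])}.  The session value is the
#' event-count-weighted mean over groups.  Computed under both quadrant
#' and ring segmentations for both instructions, these values give the
#' four reliability conditions whose equality indicates equally
#' discriminative segment maps.
#'
#' @inheritParams stimulusBetas
#' @param mode segmentation mode to evaluate (\code{"quadrant"} or
#'   \code{"ring"}); must match how \code{tcs} was extracted.
#' @return list with \code{perGroup} (data.frame of per-group contrasts)
#'   and \code{value} (the weighted session mean).
#' @export
contrastActivation <- function(tcs, trials, mode = tcs@mode, hrf = NULL,
                               nDct = 8L) {
  if (tcs@mode != mode)
    stop("time courses were extracted under a different segmentation mode")
  cd <- buildContrastDesign(trials, mode, nVolumes(tcs), tcs@volumeMs,
                            hrf = hrf, nDct = nDct)
  fit <- fitGlm(tcs, cd$design)
  contrastFromBetas(fit$beta, cd$nEvents)
}

# design for the contrast-activation fit: stimulus events grouped by their
# containing segment, each group modelled in every block (16 columns)
buildContrastDesign <- function(trials, mode, nVolumes, volumeMs,
                                hrf = NULL, nDct = 8L) {
  if (is.null(hrf)) hrf <- canonicalHrf(volumeMs)
  noS2 <- is.na(trials$s2_onset_ms)
  onsets <- c(trials$s1_onset_ms, trials$s2_onset_ms[!noS2])
  segs <- c(stimulusSegment(trials, mode, "s1"),
            stimulusSegment(trials, mode, "s2")[!noS2])
  zero <- numeric(nVolumes)
  neural <- do.call(cbind, lapply(1:4, function(j) {
    piece <- eventRegressor(onsets[segs == j], 0, nVolumes, volumeMs, hrf)
    vapply(1:4, function(k)
      stackBlocks(lapply(1:4, function(b) if (b == k) piece else zero)),
      numeric(4 * nVolumes))
  }))
  colnames(neural) <- as.vector(outer(1:4, 1:4, function(k, j)
    paste0("stim", j, "_b", k)))
  design <- new("ConcatDesign",
                design = cbind(neural, concatNuisance(nVolumes, nDct)),
                blockIndex = rep(1:4, each = nVolumes),
                neuralColumns = colnames(neural), mode = mode,
                volumeMs = volumeMs)
  list(design = design,
       nEvents = vapply(1:4, function(j) sum(segs == j), numeric(1)))
}

# per-group contrasts (own segment minus mean of the other three) from the
# 16 stimulus betas, in the column order of buildContrastDesign
contrastFromBetas <- function(betas, nEvents) {
  B <- matrix(betas[seq_len(16)], 4, 4)  # rows: block k, cols: group j
  contrasts <- vapply(1:4, function(j)
    B[j, j] - mean(B[setdiff(1:4, j), j]), numeric(1))
  list(perGroup = data.frame(segment = 1:4, contrast = contrasts,
                             n_events = nEvents),
       value = sum(contrasts * nEvents) / sum(nEvents))
}
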