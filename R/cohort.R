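#' Precompute a reusable session template for simulation studies
#'
#' Calibration and power studies refit the same first-level designs
#' thousands of times.  This helper generates one session per instruction
#' (trial sequence, resolved regions, concatenated delay design and
#' contrast-activation designs under both segmentation modes) and caches
#' the QR decompositions, so replicate fits reduce to applying the stored
#' decomposition to fresh data.
#'
#' @param seed integer seed for the trial sequences.
#' @param volumeMs task acquisition interval in ms.
#' @param nDct DCT columns per segment block.
#' @param protocol a [MappingProtocol-class] (for the stimulus geometry).
#' @return list with the trial tables, regions, designs and QR caches.
#' @export
sessionTemplate <- function(seed = 1L, volumeMs = 1500, nDct = 8L,
                            protocol = mappingProtocol()) {
  withr::local_seed(seed)
  seeds <- sample.int(1e6, 2)
  positions <- generateStimulusPositions(protocol)
  hrf <- canonicalHrf(volumeMs)
  instructions <- c("categorical", "coordinate")
  trials <- lapply(seq_along(instructions), function(i)
    generateTrialSequence(instructions[i], positions, seed = seeds[i]))
  names(trials) <- instructions
  regions <- lapply(trials, resolveRegions)
  nVol <- vapply(trials, sessionVolumes, integer(1), volumeMs = volumeMs)
  delayDesign <- lapply(instructions, function(ins)
    buildConcatenatedDesign(trials[[ins]], regions[[ins]], nVol[[ins]],
                            volumeMs, hrf = hrf, nDct = nDct))
  names(delayDesign) <- instructions
  delayQr <- lapply(delayDesign, function(d) qr(designMatrix(d)))
  contrastDesign <- lapply(instructions, function(ins) {
    out <- lapply(c("quadrant", "ring"), function(m)
      buildContrastDesign(trials[[ins]], m, nVol[[ins]], volumeMs,
                          hrf = hrf, nDct = nDct))
    names(out) <- c("quadrant", "ring")
    out
  })
  names(contrastDesign) <- instructions
  contrastQr <- lapply(contrastDesign, function(byMode)
    lapply(byMode, function(cd) qr(designMatrix(cd$design))))
  list(protocol = protocol, volumeMs = volumeMs, nDct = nDct, hrf = hrf,
       positions = positions, trials = trials, regions = regions,
       nVol = nVol, delayDesign = delayDesign, delayQr = delayQr,
       contrastDesign = contrastDesign, contrastQr = contrastQr)
}

# AR(1) noise for a concatenated series: the four segment blocks carry
# independent noise, filtered within each block
concatNoiseMatrix <- function(nVol, nCols, sd, rho) {
  E <- matrix(stats::rnorm(nVol * 4L * nCols), nrow = nVol)
  if (rho > 0) {
    E <- apply(E, 2, function(e)
      as.numeric(stats::filter(e, rho, method = "recursive")))
    E <- E * sqrt(1 - rho^2)
  }
  matrix(E, nrow = 4L * nVol) * sd
}

#' Simulate a cohort of delay-period beta tables
#'
#' Fast generative model for group-level calibration and power studies:
#' each subject's concatenated segment time course is built from the
#' template's actual delay design -- the matching and mismatching delay
#' regressors scaled by the (optionally area-specific, between-subject
#' variable) injected amplitudes -- plus AR(1) Gaussian noise, and is fit
#' by the stored OLS decomposition.  With zero amplitudes this is the
#' matched-null generator for type-I-error calibration of the group
#' ANOVAs.
#'
#' @param template from [sessionTemplate()].
#' @param nSubjects subjects per cohort.
#' @param delayMatchAmp,delayMismatchAmp injected amplitudes: a scalar,
#'   a named per-area vector, or a named list per instruction of either.
#' @param betweenSubjectSd SD of the subject-level amplitude variation.
#' @param noiseSd residual noise SD of the segment mean series.
#' @param ar1Rho lag-1 autocorrelation of the residual noise.
#' @param seed integer seed.
#' @param areas area labels to emit.
#' @return long-format beta table: \code{subject}, \code{area},
#'   \code{instruction}, \code{region}, \code{beta}.
#' @export
simulateCohortDelayBetas <- function(template, nSubjects,
                                     delayMatchAmp = 0,
                                     delayMismatchAmp = 0,
                                     betweenSubjectSd = 0, noiseSd = 1,
                                     ar1Rho = 0.3, seed = 1L,
                                     areas = c("V1", "V2", "V3")) {
  withr::local_seed(seed)
  instrAmp <- function(amp, ins) if (is.list(amp)) amp[[ins]] else amp
  out <- list()
  for (ins in names(template$trials)) {
    X <- designMatrix(template$delayDesign[[ins]])
    qrX <- template$delayQr[[ins]]
    xdm <- X[, "delay_match"]
    xdmm <- X[, "delay_mismatch"]
    for (a in areas) {
      am <- areaAmp(instrAmp(delayMatchAmp, ins), a)
      amm <- areaAmp(instrAmp(delayMismatchAmp, ins), a)
      ampM <- stats::rnorm(nSubjects, am, betweenSubjectSd)
      ampMM <- stats::rnorm(nSubjects, amm, betweenSubjectSd)
      Y <- outer(xdm, ampM) + outer(xdmm, ampMM) +
        concatNoiseMatrix(template$nVol[[ins]], nSubjects, noiseSd, ar1Rho)
      B <- qr.coef(qrX, Y)
      out[[length(out) + 1L]] <- data.frame(
        subject = rep(seq_len(nSubjects), each = 2L),
        area = a, instruction = ins,
        region = rep(c("match", "mismatch"), nSubjects),
        beta = as.vector(rbind(B["delay_match", ], B["delay_mismatch", ])))
    }
  }
  do.call(rbind, out)
}

#' Simulate a cohort of contrast-activation values
#'
#' Null generator for the reliability (contrast-activation) ANOVA: each
#' subject x instruction x segmentation-mode value is computed by fitting
#' the template's 16-column contrast design to AR(1) Gaussian noise and
#' reducing the betas exactly as [contrastActivation()] does.
#'
#' @inheritParams simulateCohortDelayBetas
#' @param stimAmp amplitude of a uniform stimulus response added in every
#'   group's own segment (0 keeps the conditions equal, the null of the
#'   reliability analysis).
#' @return data.frame \code{subject}, \code{instruction}, \code{mode},
#'   \code{value}.
#' @export
simulateCohortContrasts <- function(template, nSubjects, stimAmp = 0,
                                    noiseSd = 1, ar1Rho = 0.3, seed = 1L) {
  withr::local_seed(seed)
  out <- list()
  for (ins in names(template$trials)) {
    for (m in c("quadrant", "ring")) {
      cd <- template$contrastDesign[[ins]][[m]]
      X <- designMatrix(cd$design)
      qrX <- template$contrastQr[[ins]][[m]]
      own <- rowSums(X[, paste0("stim", 1:4, "_b", 1:4), drop = FALSE])
      Y <- stimAmp * own +
        concatNoiseMatrix(template$nVol[[ins]], nSubjects, noiseSd, ar1Rho)
      B <- qr.coef(qrX, Y)
      vals <- vapply(seq_len(nSubjects), function(s)
        contrastFromBetas(B[seq_len(16), s], cd$nEvents)$value, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        subject = seq_len(nSubjects), instruction = ins, mode = m,
        value = vals)
    }
  }
  do.call(rbind, out)
}
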