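#' Generate the forty dot positions of the cross-dot task
#'
#' The task stimulus is a central cross with a single dot at one of forty
#' positions: ten per quadrant, spread over four radial distances from the
#' cross centre (1.875, 3.75, 5.625 and 7.5 degrees of visual angle).
#' Within a quadrant the positions sit at two angles on each of the two
#' inner rings and three angles on each of the two outer rings, evenly
#' spaced strictly inside the quadrant so no dot ever lies on a cross arm.
#' The layout is fixed; \code{seed} is accepted for interface symmetry with
#' the other generators but does not change the positions.
#'
#' @param protocol a [MappingProtocol-class] supplying the maximum
#'   eccentricity from which the radii derive.
#' @param seed unused; the position set is deterministic.
#' @return data.frame with columns \code{position_id}, \code{quadrant},
#'   \code{ring}, \code{radius_deg}, \code{angle_deg}.
#' @examples
#' pos <- generateStimulusPositions()
#' table(pos$quadrant)  # 10 per quadrant
#' @export
generateStimulusPositions <- function(protocol = mappingProtocol(),
                                      seed = NULL) {
  radii <- stimulusRadii(protocol)
  perRing <- c(2L, 2L, 3L, 3L)  # 10 per quadrant
  rows <- do.call(rbind, lapply(1:4, function(q) {
    do.call(rbind, lapply(1:4, function(r) {
      k <- perRing[r]
      data.frame(quadrant = q, ring = r, radius_deg = radii[r],
                 angle_deg = 90 * (q - 1) + 90 * seq_len(k) / (k + 1))
    }))
  }))
  rows$position_id <- seq_len(nrow(rows))
  rows[, c("position_id", "quadrant", "ring", "radius_deg", "angle_deg")]
}

# quadrant diagonally opposite q (1<->3, 2<->4)
oppositeQuadrant <- function(q) (q + 1L) %% 4L + 1L

# trial phase durations in ms (fixation, stimulus, response window, ITI)
trialTiming <- function()
  list(fixMs = 1000, stimMs = 300, respMs = 2000, itiMs = 10000,
       jitterGridMs = seq(3000, 8000, by = 1000))

#' Generate one session's trial sequence
#'
#' Builds the 80-trial session of the cross-dot working-memory task: 40
#' match, 30 non-match and 10 catch trials in random order.  Every one of
#' the forty dot positions is used exactly twice as the first stimulus
#' (S1).  The second stimulus (S2) of a match trial satisfies the active
#' instruction's match rule -- the diagonally opposite quadrant under the
#' categorical instruction, the same radial distance (any quadrant) under
#' the coordinate instruction -- while a non-match S2 violates it; catch
#' trials have no S2 and require no response.  Each trial runs fixation
#' (1000 ms), S1 (300 ms), a retention interval jittered uniformly on a
#' 1000 ms grid over 3000--8000 ms, S2 (300 ms) and a 2000 ms response
#' window, followed by a 10,000 ms inter-trial interval.
#'
#' @param instruction \code{"categorical"} or \code{"coordinate"}.
#' @param positions position set from [generateStimulusPositions()].
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @return data.frame with one row per trial: identifiers, S1/S2 geometry,
#'   onsets (ms), jitter and the correct response.  The attribute
#'   \code{sessionEndMs} gives the session duration including the final
#'   inter-trial interval.
#' @export
generateTrialSequence <- function(instruction, positions, seed = 1L) {
  instruction <- match.arg(instruction, c("categorical", "coordinate"))
  withr::local_seed(seed)
  tt <- trialTiming()
  s1pool <- positions[sample(rep(seq_len(nrow(positions)), 2L)), ]
  types <- sample(rep(c("match", "nonmatch", "catch"), c(40L, 30L, 10L)))
  n <- length(types)
  pickS2 <- function(type, s1) {
    if (type == "catch") return(NA_integer_)
    ok <- if (instruction == "categorical")
      positions$quadrant == oppositeQuadrant(s1$quadrant)
    else positions$ring == s1$ring
    if (type == "nonmatch") ok <- !ok
    cand <- positions$position_id[ok]
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  s2id <- vapply(seq_len(n), function(i)
    pickS2(types[i], s1pool[i, ]), integer(1))
  s2 <- positions[match(s2id, positions$position_id), ]
  jitter <- sample(tt$jitterGridMs, n, replace = TRUE)
  s1on <- numeric(n); t0 <- 0
  for (i in seq_len(n)) {
    s1on[i] <- t0 + tt$fixMs
    t0 <- s1on[i] + tt$stimMs + jitter[i] + tt$stimMs + tt$respMs + tt$itiMs
  }
  trials <- data.frame(
    trial_id = seq_len(n), instruction = instruction, trial_type = types,
    s1_position = s1pool$position_id, s1_quadrant = s1pool$quadrant,
    s1_ring = s1pool$ring, s1_radius = s1pool$radius_deg,
    s1_angle = s1pool$angle_deg,
    s2_position = s2id, s2_quadrant = s2$quadrant, s2_ring = s2$ring,
    s2_radius = s2$radius_deg, s2_angle = s2$angle_deg,
    jitter_ms = jitter, s1_onset_ms = s1on,
    s2_onset_ms = ifelse(types == "catch", NA_real_,
                         s1on + tt$stimMs + jitter),
    correct_response = c(match = "match", nonmatch = "nonmatch",
                         catch = "none")[types],
    row.names = NULL)
  attr(trials, "sessionEndMs") <- t0
  trials
}

# Retention-interval window of every trial: S1 offset to S2 onset.  Catch
# trials have no S2; their delay boxcar is truncated at the modeled S2 time
# of a median-jitter trial (5500 ms after S1 offset).
delayWindow <- function(trials) {
  tt <- trialTiming()
  start <- trials$s1_onset_ms + tt$stimMs
  end <- ifelse(is.na(trials$s2_onset_ms),
                start + stats::median(tt$jitterGridMs),
                trials$s2_onset_ms)
  data.frame(trial_id = trials$trial_id, start_ms = start, end_ms = end)
}

# session length in volumes at a given sampling interval
sessionVolumes <- function(trials, volumeMs) {
  endMs <- attr(trials, "sessionEndMs")
  if (is.null(endMs)) {
    tt <- trialTiming()
    last <- max(ifelse(is.na(trials$s2_onset_ms),
                       trials$s1_onset_ms + tt$stimMs + max(tt$jitterGridMs),
                       trials$s2_onset_ms) + tt$stimMs + tt$respMs)
    endMs <- last + tt$itiMs
  }
  as.integer(ceiling(endMs / volumeMs))
}

#' Read or write a BIDS-style events table
#'
#' Serialises a trial table (or any per-trial/per-event data.frame) as a
#' tab-separated events file with \code{onset} and \code{duration} in
#' seconds followed by the remaining columns.
#'
#' @param trials trial table from [generateTrialSequence()].
#' @param path file path of the TSV.
#' @return \code{readEventsTsv} returns the trial table with onsets in ms
#'   restored; \code{writeEventsTsv} returns \code{path} invisibly.
#' @export
writeEventsTsv <- function(trials, path) {
  tt <- trialTiming()
  out <- data.frame(onset = trials$s1_onset_ms / 1000,
                    duration = tt$stimMs / 1000,
                    trials[, setdiff(names(trials),
                                     c("s1_onset_ms", "s2_onset_ms"))],
                    s1_onset = trials$s1_onset_ms / 1000,
                    s2_onset = trials$s2_onset_ms / 1000)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  x <- utils::read.delim(path, sep = "\t")
  x$s1_onset_ms <- x$s1_onset * 1000
  x$s2_onset_ms <- x$s2_onset * 1000
  x$onset <- x$duration <- x$s1_onset <- x$s2_onset <- NULL
  x
}
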