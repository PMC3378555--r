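#' Simulate behavioural responses for a session
#'
#' Generates one response per scored (non-catch) trial: a Bernoulli correct
#' flag with the instruction's accuracy probability, and a log-normal
#' response time with the stated mean and SD.  Catch trials require no
#' response and never appear in the output.
#'
#' @param trials trial table from [generateTrialSequence()].
#' @param accByInstruction named probabilities of a correct response, one
#'   entry per instruction.
#' @param rtParams named list of \code{c(mean, sd)} response-time
#'   parameters in ms per instruction.
#' @param seed integer seed.
#' @return data.frame with one row per scored trial: \code{trial_id},
#'   \code{instruction}, \code{trial_type}, \code{response},
#'   \code{correct}, \code{rt_ms}.
#' @export
simulateBehavior <- function(trials,
                             accByInstruction = c(categorical = 0.95,
                                                  coordinate = 0.80),
                             rtParams = list(
                               categorical = c(mean = 900, sd = 180),
                               coordinate = c(mean = 1080, sd = 230)),
                             seed = 1L) {
  instr <- trials$instruction[1]
  acc <- accByInstruction[[instr]]
  if (is.null(acc) || acc <= 0 || acc > 1)
    stop("accuracy for instruction '", instr, "' must lie in (0, 1]")
  rp <- rtParams[[instr]]
  scored <- trials[trials$trial_type != "catch", ]
  withr::local_seed(seed)
  n <- nrow(scored)
  correct <- stats::runif(n) < acc
  # log-normal parameterised to match the requested mean and SD
  sdlog <- sqrt(log(1 + (rp[["sd"]] / rp[["mean"]])^2))
  meanlog <- log(rp[["mean"]]) - sdlog^2 / 2
  rt <- stats::rlnorm(n, meanlog, sdlog)
  flip <- c(match = "nonmatch", nonmatch = "match")
  data.frame(trial_id = scored$trial_id, instruction = instr,
             trial_type = scored$trial_type,
             response = ifelse(correct, scored$correct_response,
                               flip[scored$correct_response]),
             correct = correct, rt_ms = rt, row.names = NULL)
}

#' Score a behavioural table
#'
#' Aggregates one session's simulated responses into the subject-level
#' summary used by the group tests: percent correct over the seventy
#' scored trials and the mean response time of correct trials.
#'
#' @param behavior output of [simulateBehavior()].
#' @return one-row data.frame with \code{instruction}, \code{accuracy}
#'   (percent) and \code{mean_rt_ms}.
#' @export
scoreBehavior <- function(behavior) {
  data.frame(instruction = behavior$instruction[1],
             accuracy = 100 * mean(behavior$correct),
             mean_rt_ms = mean(behavior$rt_ms[behavior$correct]))
}
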