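#' Default run configuration
#'
#' Returns the pipeline's default configuration as a named list, optionally
#' updated from a YAML file and/or an override list.  Every stochastic
#' stage draws its seed from the single top-level \code{seed}, so a config
#' file fully determines a run; the config is echoed into the run
#' directory and round-trips losslessly through YAML.
#'
#' @param path optional YAML file with (a subset of) the configuration.
#' @param overrides named list applied on top of the file values.
#' @return configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(
    n_subjects = 10L, n_per_area = 160L, seed = 1L,
    volume_ms_task = 1500, noise_sd = 1, gain = 1, alpha = 0.05,
    n_dct = 8L, exclude_s1_quadrant = TRUE, between_subject_sd = 0.1,
    effects = list(amp_s1 = 1.5, amp_s2 = 1.5,
                   delay_match_amp = list(
                     categorical = list(V1 = 0, V2 = 0.15, V3 = 0.3),
                     coordinate = 0.1),
                   delay_mismatch_amp = list(categorical = 0,
                                             coordinate = 0.1),
                   ecc_amp = 0.1, ar1_rho = 0.3,
                   drift = c(0.5, 0.5), mapping_amp = 3),
    behavior = list(acc = list(categorical = 0.95, coordinate = 0.80),
                    rt_mean = list(categorical = 900, coordinate = 1080),
                    rt_sd = list(categorical = 180, coordinate = 230)))
  deepMerge <- function(base, upd) {
    for (nm in names(upd))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        deepMerge(base[[nm]], upd[[nm]]) else upd[[nm]]
    base
  }
  if (!is.null(path)) cfg <- deepMerge(cfg, yaml::read_yaml(path))
  deepMerge(cfg, overrides)
}

# resolve a delay amplitude for one instruction: a scalar, a per-area
# list/vector, or a per-instruction list of either
resolveDelayAmp <- function(x, instruction) {
  if (is.list(x) &&
      any(names(x) %in% c("categorical", "coordinate")))
    x <- x[[instruction]]
  if (is.list(x)) unlist(x) else x
}

effectsFromConfig <- function(cfg, instruction = "categorical") {
  e <- cfg$effects
  effectSpec(ampS1 = e$amp_s1, ampS2 = e$amp_s2,
             delayMatchAmp = resolveDelayAmp(e$delay_match_amp, instruction),
             delayMismatchAmp = resolveDelayAmp(e$delay_mismatch_amp,
                                                instruction),
             eccAmp = e$ecc_amp, ar1Rho = e$ar1_rho,
             driftCoeffs = as.numeric(e$drift), mappingAmp = e$mapping_amp)
}

# add subject-level variability to a (possibly per-area) delay amplitude
perturbAmp <- function(amp, sd) {
  if (sd <= 0) return(amp)
  amp + stats::rnorm(length(amp), 0, sd)
}

#' Simulate and analyse one subject end to end
#'
#' Runs the complete single-subject pipeline on synthetic data: voxel
#' sheet, wedge and ring mapping runs, cross-correlation phase maps with
#' Bonferroni masking, quadrant and ring segment maps, one task session
#' per instruction, concatenated-segment GLM fits for the three areas,
#' stimulus-split betas, contrast-activation values, and scored behaviour.
#'
#' @param seed integer seed; all stage seeds derive from it.
#' @param config configuration list from [readRunConfig()].
#' @param protocol a [MappingProtocol-class].
#' @return list of data.frames: \code{delay}, \code{stimulus},
#'   \code{contrasts}, \code{behavior}, \code{retinotopy} (per-run
#'   diagnostic counts), plus the per-subject \code{events} tables.
#' @export
runSubject <- function(seed, config = readRunConfig(),
                       protocol = mappingProtocol()) {
  withr::local_seed(seed)
  seeds <- sample.int(1e6, 16)
  effects <- lapply(c(categorical = "categorical",
                      coordinate = "coordinate"), function(ins) {
    e <- effectsFromConfig(config, ins)
    e@delayMatchAmp <- perturbAmp(e@delayMatchAmp,
                                  config$between_subject_sd)
    e@delayMismatchAmp <- perturbAmp(e@delayMismatchAmp,
                                     config$between_subject_sd)
    e
  })
  sheet <- generateVoxelSheet(config$n_per_area, protocol, seed = seeds[1],
                              gain = config$gain, noiseSd = config$noise_sd)
  hrfMap <- canonicalHrf(protocol@volumeMs)
  hrfTask <- canonicalHrf(config$volume_ms_task)
  runs <- list(
    wedge = simulateMappingSeries(sheet, protocol, "wedge",
                                  effects$categorical, seed = seeds[2],
                                  hrf = hrfMap),
    ring = simulateMappingSeries(sheet, protocol, "ring",
                                 effects$categorical, seed = seeds[3],
                                 hrf = hrfMap))
  est <- lapply(runs, function(r)
    significanceMask(crosscorrMap(dctHighpass(r), protocol, hrfMap),
                     alpha = config$alpha))
  segmaps <- list(quadrant = assignPolarSegments(est$wedge),
                  ring = assignEccSegments(est$ring))
  positions <- generateStimulusPositions(protocol)
  instructions <- c("categorical", "coordinate")
  areas <- c("V1", "V2", "V3")
  delay <- stimulus <- contrasts <- behavior <- events <- list()
  for (i in seq_along(instructions)) {
    ins <- instructions[i]
    trials <- generateTrialSequence(ins, positions, seed = seeds[3 + i])
    series <- simulateTaskSeries(sheet, trials, effects[[ins]],
                                 seed = seeds[5 + i],
                                 volumeMs = config$volume_ms_task,
                                 hrf = hrfTask)
    regions <- resolveRegions(trials,
                              excludeS1Quadrant = config$exclude_s1_quadrant)
    nVol <- nVolumes(series)
    design <- buildConcatenatedDesign(trials, regions, nVol,
                                      config$volume_ms_task, hrf = hrfTask,
                                      nDct = config$n_dct)
    nativeMode <- regions$mode[1]
    for (a in areas) {
      tcs <- extractSegmentTimecourses(series, segmaps[[nativeMode]], a)
      fit <- fitGlm(tcs, design)
      dm <- fit$beta[fit$factor == "delay_match"]
      dmm <- fit$beta[fit$factor == "delay_mismatch"]
      delay[[length(delay) + 1L]] <- data.frame(
        area = a, instruction = ins, region = c("match", "mismatch"),
        beta = c(dm, dmm))
      sb <- stimulusBetas(tcs, trials, regions, hrf = hrfTask,
                          nDct = config$n_dct)
      stimulus[[length(stimulus) + 1L]] <- data.frame(
        area = a, instruction = ins, stimulus = sb$factor, beta = sb$beta)
    }
    for (m in c("quadrant", "ring")) {
      vals <- vapply(areas, function(a) {
        tcsM <- extractSegmentTimecourses(series, segmaps[[m]], a)
        contrastActivation(tcsM, trials, m, hrf = hrfTask,
                           nDct = config$n_dct)$value
      }, numeric(1))
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        instruction = ins, mode = m, value = mean(vals))
    }
    beh <- simulateBehavior(trials,
                            accByInstruction = unlist(config$behavior$acc),
                            rtParams = list(
                              categorical = c(
                                mean = config$behavior$rt_mean$categorical,
                                sd = config$behavior$rt_sd$categorical),
                              coordinate = c(
                                mean = config$behavior$rt_mean$coordinate,
                                sd = config$behavior$rt_sd$coordinate)),
                            seed = seeds[7 + i])
    behavior[[length(behavior) + 1L]] <- scoreBehavior(beh)
    events[[ins]] <- trials
  }
  retino <- do.call(rbind, lapply(names(est), function(s) data.frame(
    stimulus = s, n_voxels = nrow(est[[s]]),
    n_significant = sum(est[[s]]$significant))))
  list(delay = do.call(rbind, delay), stimulus = do.call(rbind, stimulus),
       contrasts = do.call(rbind, contrasts),
       behavior = do.call(rbind, behavior), retinotopy = retino,
       events = events)
}

#' Simulate and analyse a cohort
#'
#' Applies [runSubject()] to \code{nSubjects} derived seeds and stacks the
#' per-subject tables.
#'
#' @param nSubjects number of subjects.
#' @param seed cohort seed; per-subject seeds derive from it.
#' @inheritParams runSubject
#' @return list of long-format data.frames (\code{delay},
#'   \code{stimulus}, \code{contrasts}, \code{behavior},
#'   \code{retinotopy}) with a \code{subject} column, and the per-subject
#'   \code{events} tables.
#' @export
simulateCohort <- function(nSubjects, seed = 1L, config = readRunConfig(),
                           protocol = mappingProtocol()) {
  withr::local_seed(seed)
  subjSeeds <- sample.int(1e6, nSubjects)
  per <- lapply(seq_len(nSubjects), function(s)
    runSubject(subjSeeds[s], config = config, protocol = protocol))
  bind <- function(name) do.call(rbind, lapply(seq_along(per), function(s)
    cbind(subject = s, per[[s]][[name]])))
  list(delay = bind("delay"), stimulus = bind("stimulus"),
       contrasts = bind("contrasts"), behavior = bind("behavior"),
       retinotopy = bind("retinotopy"),
       events = lapply(per, `[[`, "events"))
}

#' Group-level statistics for a cohort
#'
#' Runs the full second-level battery: the three-way (area x instruction x
#' region) repeated-measures ANOVA on the delay betas, per-area follow-ups
#' with post-hoc contrasts, the per-area instruction x stimulus ANOVA on
#' the stimulus betas, paired behavioural t-tests, and the
#' contrast-activation reliability ANOVA.
#'
#' @param cohort list from [simulateCohort()] (or equivalently shaped
#'   tables).
#' @return named list of result tables.
#' @export
cohortStats <- function(cohort) {
  out <- list()
  out$delay_anova <- rmAnova(cohort$delay, dv = "beta",
                             subject = "subject",
                             within = c("area", "instruction", "region"))
  fu <- followupPerRoi(cohort$delay)
  out$followup_anova <- fu$anova
  out$followup_posthoc <- fu$posthoc
  out$stimulus_anova <- do.call(rbind, lapply(
    sort(unique(cohort$stimulus$area)), function(a)
      cbind(area = a,
            rmAnova(cohort$stimulus[cohort$stimulus$area == a, ],
                    dv = "beta", subject = "subject",
                    within = c("instruction", "stimulus")))))
  if (!is.null(cohort$behavior))
    out$behavioral_tests <- behavioralTests(cohort$behavior)
  ca <- contrastActivationAnova(cohort$contrasts)
  out$contrast_anova_oneway <- ca$oneway
  out$contrast_anova_factorial <- ca$factorial
  out
}

#' Run the full pipeline into a directory
#'
#' Orchestrates \code{simulate -> map -> segment -> fit -> stats ->
#' report} for a whole cohort, writing per-stage TSV outputs, a YAML echo
#' of the configuration and a JSON manifest (config hash, seeds, stage
#' outputs, versions).  Rerunning with the same configuration reproduces
#' all result tables bit-identically.
#'
#' @param config configuration list from [readRunConfig()] or the path of
#'   a YAML config file.
#' @param outDir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = readRunConfig(), outDir, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTsv <- function(x, path) {
    x$mismatching_segments <- NULL
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  cohort <- simulateCohort(config$n_subjects, seed = config$seed,
                           config = config)
  stages <- list()
  evDir <- file.path(outDir, "events")
  dir.create(evDir, showWarnings = FALSE)
  for (s in seq_along(cohort$events))
    for (ins in names(cohort$events[[s]]))
      writeEventsTsv(cohort$events[[s]][[ins]],
                     file.path(evDir, sprintf("sub-%02d_task-%s_events.tsv",
                                              s, ins)))
  stages$simulate <- c("events/",
                       writeTsv(cohort$behavior,
                                file.path(outDir, "behavior.tsv")))
  stages$map <- writeTsv(cohort$retinotopy,
                         file.path(outDir, "retinotopy_summary.tsv"))
  stages$segment <- writeTsv(cohort$retinotopy,
                             file.path(outDir, "segment_summary.tsv"))
  stages$fit <- c(
    writeTsv(cohort$delay, file.path(outDir, "delay_betas.tsv")),
    writeTsv(cohort$stimulus, file.path(outDir, "stimulus_betas.tsv")),
    writeTsv(cohort$contrasts,
             file.path(outDir, "contrast_activation.tsv")))
  stats <- cohortStats(cohort)
  statsDir <- file.path(outDir, "stats")
  dir.create(statsDir, showWarnings = FALSE)
  stages$stats <- vapply(names(stats), function(nm)
    writeTsv(stats[[nm]], file.path(statsDir, paste0(nm, ".tsv"))),
    character(1))
  stages$report <- makeReport(outDir)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  manifest <- list(config = config, config_hash = rlang::hash(config),
                   seed = config$seed,
                   stages = lapply(stages, basename),
                   n_stage_outputs = length(stages),
                   package_version = as.character(
                     utils::packageVersion("retinowm")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a human-readable report for a run directory
#'
#' Collects the statistics tables written by [runPipeline()] into a
#' markdown report with one section per analysis: behavioural
#' performance, the delay-period three-way ANOVA, per-area follow-ups,
#' the stimulus-response ANOVA and the contrast-activation reliability
#' check, each with mean +/- SEM condition summaries.  Sections whose
#' inputs are absent are marked as not available.  Optionally writes
#' bar-chart figures (mean with SEM error bars) alongside the report.
#' Regeneration is idempotent.
#'
#' @param runDir a directory produced by [runPipeline()].
#' @param figures also write ggplot2 bar charts as PNG (skipped with a
#'   note if no graphics device is available).
#' @return the report path, invisibly.
#' @export
makeReport <- function(runDir, figures = FALSE) {
  readTsv <- function(name) {
    p <- file.path(runDir, name)
    if (file.exists(p)) utils::read.delim(p) else NULL
  }
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  meanSem <- function(df, value, groups) {
    agg <- stats::aggregate(df[[value]], df[groups], function(x)
      c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x))))
    cbind(agg[groups], mean = agg$x[, "mean"], sem = agg$x[, "sem"])
  }
  lines <- c("# Retinotopic working-memory pipeline report", "")
  beh <- readTsv("behavior.tsv")
  behTests <- readTsv("stats/behavioral_tests.tsv")
  lines <- c(lines, "## Behavioural performance", "")
  if (is.null(beh)) {
    lines <- c(lines, "_Not available for this run._", "")
  } else {
    lines <- c(lines, fmt(meanSem(beh, "accuracy", "instruction")), "",
               fmt(meanSem(beh, "mean_rt_ms", "instruction")), "")
    if (!is.null(behTests))
      lines <- c(lines, "Paired t-tests (categorical vs coordinate):", "",
                 fmt(behTests), "")
  }
  delay <- readTsv("delay_betas.tsv")
  lines <- c(lines, "## Delay-period activity", "")
  if (is.null(delay)) {
    lines <- c(lines, "_Not available for this run._", "")
  } else {
    lines <- c(lines,
               "Mean delay beta (+/- SEM) per area, instruction, region:",
               "",
               fmt(meanSem(delay, "beta", c("area", "instruction",
                                            "region"))), "")
    an <- readTsv("stats/delay_anova.tsv")
    if (!is.null(an))
      lines <- c(lines, "Three-way repeated-measures ANOVA:", "",
                 fmt(an), "")
    fu <- readTsv("stats/followup_anova.tsv")
    ph <- readTsv("stats/followup_posthoc.tsv")
    if (!is.null(fu))
      lines <- c(lines, "Per-area follow-up ANOVAs:", "", fmt(fu), "")
    if (!is.null(ph))
      lines <- c(lines, "Post-hoc paired contrasts:", "", fmt(ph), "")
  }
  stim <- readTsv("stimulus_betas.tsv")
  lines <- c(lines, "## Stimulus-related activity", "")
  if (is.null(stim)) {
    lines <- c(lines, "_Not available for this run._", "")
  } else {
    lines <- c(lines, fmt(meanSem(stim, "beta", c("area", "instruction",
                                                  "stimulus"))), "")
    sa <- readTsv("stats/stimulus_anova.tsv")
    if (!is.null(sa))
      lines <- c(lines, "Instruction x stimulus ANOVA per area:", "",
                 fmt(sa), "")
  }
  ca <- readTsv("contrast_activation.tsv")
  lines <- c(lines, "## Contrast activation (segment-map reliability)", "")
  if (is.null(ca)) {
    lines <- c(lines, "_Not available for this run._", "")
  } else {
    lines <- c(lines, fmt(meanSem(ca, "value", c("instruction", "mode"))),
               "")
    cao <- readTsv("stats/contrast_anova_oneway.tsv")
    if (!is.null(cao))
      lines <- c(lines, "One-way ANOVA over the four conditions:", "",
                 fmt(cao), "")
  }
  if (figures && !is.null(delay)) {
    ok <- tryCatch({
      ms <- meanSem(delay, "beta", c("area", "instruction", "region"))
      p <- ggplot2::ggplot(ms, ggplot2::aes(
        x = interaction(.data$instruction, .data$region),
        y = .data$mean, fill = .data$region)) +
        ggplot2::geom_col() +
        ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
          width = 0.25) +
        ggplot2::facet_wrap(~area) +
        ggplot2::labs(x = NULL, y = "delay beta (signal units)") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(runDir, "delay_betas.png"), p,
                      width = 7, height = 3.2, dpi = 120)
      TRUE
    }, error = function(e) FALSE)
    if (ok)
      lines <- c(lines, "![Delay betas](delay_betas.png)", "")
  }
  path <- file.path(runDir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
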