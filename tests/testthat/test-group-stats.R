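test_that("rmAnova reproduces aov and car on the same data", {
  withr::local_seed(12)
  d <- expand.grid(subject = factor(1:10), area = c("V1", "V2", "V3"),
                   instruction = c("categorical", "coordinate"),
                   region = c("match", "mismatch"))
  d$beta <- rnorm(nrow(d)) + as.numeric(d$area) * 0.2
  mine <- rmAnova(d, dv = "beta", subject = "subject",
                  within = c("area", "instruction", "region"))
  expect_equal(nrow(mine), 7L)  # 3 mains, 3 two-way, 1 three-way

  a <- summary(stats::aov(beta ~ area * instruction * region +
                            Error(subject / (area * instruction * region)),
                          data = d))
  aovF <- function(term) {
    tab <- a[[paste0("Error: subject:", term)]][[1]]
    tab$`F value`[1]
  }
  for (term in c("area", "instruction", "region",
                 "area:instruction:region"))
    expect_equal(mine$F[mine$effect == term], aovF(term),
                 tolerance = 1e-10)

  # multivariate branch against car's Hotelling-Lawley approximation
  cells <- expand.grid(area = c("V1", "V2", "V3"),
                       instruction = c("categorical", "coordinate"),
                       region = c("match", "mismatch"))
  Y <- matrix(NA_real_, 10, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- d$area == cells$area[i] & d$instruction == cells$instruction[i] &
      d$region == cells$region[i]
    Y[, i] <- d$beta[sel][order(d$subject[sel])]
  }
  ca <- car::Anova(stats::lm(Y ~ 1), idata = cells,
                   idesign = ~ area * instruction * region, type = 3)
  s <- suppressWarnings(summary(ca, multivariate = TRUE))
  mv <- s$multivariate.tests$`area:instruction:region`
  hl <- sum(diag(solve(mv$SSPE) %*% mv$SSPH))  # Hotelling-Lawley trace
  FmvCar <- hl * (10 - 2) / 2  # Hotelling-Lawley exact F for q = 2, n = 10
  expect_equal(mine$F_mv[mine$effect == "area:instruction:region"], FmvCar,
               tolerance = 1e-8)
  expect_equal(mine[mine$effect == "area:instruction:region", "df1_mv"], 2)
  expect_equal(mine[mine$effect == "area:instruction:region", "df2_mv"], 8)

  # incomplete designs are refused with the offending cells named
  expect_error(rmAnova(d[-1, ], dv = "beta", subject = "subject",
                       within = c("area", "instruction", "region")),
               "not complete")
})

test_that("constant input gives zero F throughout", {
  d <- expand.grid(subject = factor(1:6), area = c("V1", "V2", "V3"),
                   instruction = c("categorical", "coordinate"),
                   region = c("match", "mismatch"))
  d$beta <- 0.42
  res <- rmAnova(d, dv = "beta", subject = "subject",
                 within = c("area", "instruction", "region"))
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))

  cc <- expand.grid(subject = 1:6,
                    instruction = c("categorical", "coordinate"),
                    mode = c("quadrant", "ring"))
  cc$value <- 0.08
  caa <- contrastActivationAnova(cc)
  expect_true(all(caa$oneway$F == 0))
  expect_true(all(caa$factorial$F == 0))
})

test_that("relabelling regions flips the contrast but not the F", {
  tpl <- sessionTemplate(seed = 3)
  b <- simulateCohortDelayBetas(tpl, 10,
                                delayMatchAmp = list(
                                  categorical = c(V1 = 0, V2 = 0,
                                                  V3 = 0.3),
                                  coordinate = 0.1),
                                delayMismatchAmp = list(categorical = 0,
                                                        coordinate = 0.1),
                                betweenSubjectSd = 0.1, seed = 5)
  fu <- followupPerRoi(b)
  swapped <- b
  swapped$region <- ifelse(b$region == "match", "mismatch", "match")
  fu2 <- followupPerRoi(swapped)
  expect_equal(fu2$anova$F, fu$anova$F, tolerance = 1e-10)
  expect_equal(fu2$posthoc$t, -fu$posthoc$t, tolerance = 1e-10)
  expect_equal(fu2$posthoc$p, fu$posthoc$p, tolerance = 1e-10)
})

test_that("an injected V3-only categorical effect is found where injected", {
  tpl <- sessionTemplate(seed = 3)
  hitsV3 <- hitsV1 <- logical(30)
  for (i in seq_len(30)) {
    b <- simulateCohortDelayBetas(tpl, 10,
                                  delayMatchAmp = list(
                                    categorical = c(V1 = 0, V2 = 0,
                                                    V3 = 0.3),
                                    coordinate = 0.1),
                                  delayMismatchAmp = list(categorical = 0,
                                                          coordinate = 0.1),
                                  betweenSubjectSd = 0.1, seed = 100 + i)
    fu <- followupPerRoi(b)$anova
    pInt <- function(a) fu$p[fu$area == a & fu$effect ==
                               "instruction:region"]
    hitsV3[i] <- pInt("V3") < 0.05
    hitsV1[i] <- pInt("V1") < 0.05
  }
  expect_gte(mean(hitsV3), 0.8)
  expect_lte(mean(hitsV1), 0.2)
})

test_that("type-I error is near nominal under the matched null", {
  tpl <- sessionTemplate(seed = 3)
  p3 <- pPost <- numeric(150)
  for (i in seq_len(150)) {
    b <- simulateCohortDelayBetas(tpl, 10, seed = 2000 + i)
    an <- rmAnova(b, dv = "beta", subject = "subject",
                  within = c("area", "instruction", "region"))
    p3[i] <- an$p[an$effect == "area:instruction:region"]
    fu <- followupPerRoi(b)$posthoc
    pPost[i] <- fu$p[1]
  }
  # 150 replicates: keep within ~3 binomial SEs of the nominal 5%
  expect_lt(abs(mean(p3 < 0.05) - 0.05), 0.055)
  expect_lt(abs(mean(pPost < 0.05) - 0.05), 0.055)
})

test_that("behavioural tests are antisymmetric and well calibrated", {
  ps <- data.frame(subject = rep(1:10, 2),
                   instruction = rep(c("categorical", "coordinate"),
                                     each = 10),
                   accuracy = c(rnorm(10, 95, 3), rnorm(10, 80, 5)),
                   mean_rt_ms = c(rnorm(10, 900, 150),
                                  rnorm(10, 1080, 200)))
  res <- behavioralTests(ps)
  swapped <- ps
  swapped$instruction <- rep(c("coordinate", "categorical"), each = 10)
  res2 <- behavioralTests(swapped)
  expect_equal(res2$t, -res$t, tolerance = 1e-10)

  # identical conditions: t = 0 by convention
  same <- ps
  same$accuracy <- rep(same$accuracy[1:10], 2)
  same$mean_rt_ms <- rep(same$mean_rt_ms[1:10], 2)
  res0 <- behavioralTests(same)
  expect_true(all(res0$t == 0))
  expect_error(behavioralTests(ps[c(1, 11), ]), "two subjects")

  # power at a typical categorical/coordinate performance gap
  # (97% vs 81% accuracy, between-subject SDs 3.14 / 5.64, n = 10)
  withr::local_seed(77)
  sig <- vapply(1:300, function(i) {
    d <- data.frame(subject = rep(1:10, 2),
                    instruction = rep(c("categorical", "coordinate"),
                                      each = 10),
                    accuracy = c(rnorm(10, 96.86, 3.14),
                                 rnorm(10, 81.00, 5.64)),
                    mean_rt_ms = 1000)
    behavioralTests(d)$p[1] < 0.001
  }, logical(1))
  # exact noncentral-t oracle: power = 0.979 at these parameters; stay
  # within three binomial SEs of it at 300 replicates
  expect_gte(mean(sig), 0.979 - 3 * sqrt(0.979 * 0.021 / 300))
})

test_that("the reliability ANOVA stays null for equally reliable maps", {
  tpl <- sessionTemplate(seed = 3)
  pOne <- vapply(1:100, function(i) {
    cc <- simulateCohortContrasts(tpl, 10, seed = 300 + i)
    contrastActivationAnova(cc)$oneway$p[1]
  }, numeric(1))
  expect_gte(mean(pOne > 0.05), 0.88)
})
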