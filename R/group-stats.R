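#' Repeated-measures ANOVA on a fully within-subject design
#'
#' Tests every main effect and interaction of a balanced, fully
#' within-subject factorial design by reducing each subject's cell means
#' to orthonormal contrast scores.  For each effect the function reports
#' the univariate sphericity-assumed F with the conventional degrees of
#' freedom, the Greenhouse-Geisser corrected p-value, and the multivariate
#' (Hotelling) test of the same contrast with degrees of freedom
#' (q, n - q), where q is the effect's contrast dimension.  Both variants
#' are emitted because second-level fMRI analyses report sometimes one,
#' sometimes the other; for single-degree-of-freedom effects they
#' coincide.
#'
#' @param data long-format data.frame: one row per subject x cell.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject identifier column.
#' @param within character vector of within-subject factor columns.
#' @return data.frame with one row per effect: \code{effect}, univariate
#'   \code{df1}, \code{df2}, \code{F}, \code{p}, \code{gg_epsilon},
#'   \code{p_gg}, and multivariate \code{df1_mv}, \code{df2_mv},
#'   \code{F_mv}, \code{p_mv}.
#' @examples
#' d <- expand.grid(subject = 1:8, a = c("x", "y"), b = c("u", "v"))
#' d$y <- rnorm(nrow(d))
#' rmAnova(d, dv = "y", subject = "subject", within = c("a", "b"))
#' @export
rmAnova <- function(data, dv = "beta", subject = "subject",
                    within = c("area", "instruction", "region")) {
  fac <- lapply(within, function(w) factor(data[[w]]))
  names(fac) <- within
  levs <- lapply(fac, levels)
  cells <- interaction(rev(fac), lex.order = TRUE)  # last factor slowest
  tab <- table(factor(data[[subject]]), cells)
  if (any(tab != 1L)) {
    bad <- colnames(tab)[colSums(tab != 1L) > 0]
    stop("design is not complete and balanced; problem cell(s): ",
         paste(bad, collapse = ", "))
  }
  subj <- factor(data[[subject]])
  n <- nlevels(subj)
  # Y: subjects x cells, first within factor varying fastest
  ord <- order(subj, cells)
  Y <- matrix(data[[dv]][ord], nrow = n, byrow = TRUE)
  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  out <- do.call(rbind, lapply(effects, function(eff) {
    mats <- lapply(within, function(w) {
      L <- length(levs[[w]])
      if (w %in% eff) orthonormalContrasts(L)
      else matrix(1 / sqrt(L), L, 1)
    })
    C <- Reduce(function(a, b) kronecker(b, a), mats)
    scoreTest(Y %*% C, paste(eff, collapse = ":"), n)
  }))
  rownames(out) <- NULL
  out
}

orthonormalContrasts <- function(L) {
  C <- stats::contr.poly(L)
  C / rep(sqrt(colSums(C^2)), each = L)
}

# univariate and multivariate tests that the mean contrast score is zero
scoreTest <- function(U, label, n) {
  q <- ncol(U)
  ubar <- colMeans(U)
  Uc <- sweep(U, 2, ubar)
  ssEff <- n * sum(ubar^2)
  ssErr <- sum(Uc^2)
  df1 <- q
  df2 <- q * (n - 1)
  if (ssEff < 1e-12 && ssErr < 1e-12) {
    Fu <- 0; p <- 1; eps <- 1; Fm <- 0; pm <- 1
  } else {
    Fu <- (ssEff / df1) / (ssErr / df2)
    p <- stats::pf(Fu, df1, df2, lower.tail = FALSE)
    S <- crossprod(Uc) / (n - 1)
    eps <- sum(diag(S))^2 / (q * sum(S * S))
    eps <- min(max(eps, 1 / q), 1)
    Sinv <- tryCatch(solve(S), error = function(e) NULL)
    if (!is.null(Sinv) && n > q) {
      T2 <- n * drop(t(ubar) %*% Sinv %*% ubar)
      Fm <- (n - q) / (q * (n - 1)) * T2
      pm <- stats::pf(Fm, q, n - q, lower.tail = FALSE)
    } else {
      Fm <- NA_real_; pm <- NA_real_
    }
  }
  data.frame(effect = label, df1 = df1, df2 = df2, F = Fu, p = p,
             gg_epsilon = eps,
             p_gg = if (is.na(Fu)) NA_real_ else
               stats::pf(Fu, df1 * eps, df2 * eps, lower.tail = FALSE),
             df1_mv = q, df2_mv = n - q, F_mv = Fm, p_mv = pm)
}

#' Per-area follow-up of the delay-period analysis
#'
#' For each visual area, runs the 2 x 2 repeated-measures ANOVA with
#' instruction and region as within-subject factors, and paired post-hoc
#' contrasts of matching versus mismatching region within each
#' instruction.  Post-hoc p-values are reported both uncorrected and
#' Holm-adjusted across the contrasts of each area.
#'
#' @param betas long-format delay beta table with columns \code{subject},
#'   \code{area}, \code{instruction}, \code{region} (match/mismatch) and
#'   \code{beta}.
#' @return list with \code{anova} (per-area effect table) and
#'   \code{posthoc} (per-area, per-instruction paired contrasts).
#' @export
followupPerRoi <- function(betas) {
  areas <- sort(unique(betas$area))
  anova <- do.call(rbind, lapply(areas, function(a) {
    res <- rmAnova(betas[betas$area == a, ], dv = "beta",
                   subject = "subject", within = c("instruction", "region"))
    cbind(area = a, res)
  }))
  posthoc <- do.call(rbind, lapply(areas, function(a) {
    rows <- do.call(rbind, lapply(unique(betas$instruction), function(ins) {
      d <- betas[betas$area == a & betas$instruction == ins, ]
      w <- stats::reshape(d[, c("subject", "region", "beta")],
                          direction = "wide", idvar = "subject",
                          timevar = "region")
      tt <- stats::t.test(w$beta.match, w$beta.mismatch, paired = TRUE)
      data.frame(area = a, instruction = ins,
                 mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 direction = if (tt$estimate > 0) "match > mismatch"
                             else "match <= mismatch")
    }))
    rows$p_holm <- stats::p.adjust(rows$p, method = "holm")
    rows
  }))
  rownames(posthoc) <- NULL
  list(anova = anova, posthoc = posthoc)
}

#' Paired behavioural comparisons between instructions
#'
#' Paired t-tests comparing the two task instructions on subject-level
#' accuracy and mean response time.  Differences are categorical minus
#' coordinate, so positive accuracy differences and negative RT
#' differences indicate better/faster categorical performance.
#'
#' @param perSubject data.frame with columns \code{subject},
#'   \code{instruction}, \code{accuracy}, \code{mean_rt_ms} (one row per
#'   subject x instruction), e.g. stacked outputs of [scoreBehavior()].
#' @return data.frame with one row per measure: \code{measure},
#'   \code{mean_diff}, \code{t}, \code{df}, \code{p}, \code{direction}.
#' @export
behavioralTests <- function(perSubject) {
  if (length(unique(perSubject$subject)) < 2)
    stop("at least two subjects are required for a paired test")
  one <- function(col, measure) {
    w <- stats::reshape(perSubject[, c("subject", "instruction", col)],
                        direction = "wide", idvar = "subject",
                        timevar = "instruction")
    d <- w[[paste0(col, ".categorical")]] - w[[paste0(col, ".coordinate")]]
    if (stats::sd(d) < .Machine$double.eps^0.5) {
      # degenerate paired sample (identical conditions): t is 0 by
      # convention when the mean difference is also zero
      res <- list(estimate = mean(d),
                  statistic = if (abs(mean(d)) < 1e-12) 0 else
                    sign(mean(d)) * Inf,
                  parameter = length(d) - 1,
                  p.value = if (abs(mean(d)) < 1e-12) 1 else 0)
    } else {
      res <- stats::t.test(d)
    }
    data.frame(measure = measure, mean_diff = unname(res$estimate),
               t = unname(res$statistic), df = unname(res$parameter),
               p = res$p.value,
               direction = if (res$estimate > 0)
                 "categorical > coordinate" else "categorical <= coordinate")
  }
  rbind(one("accuracy", "accuracy"), one("mean_rt_ms", "response_time"))
}

#' ANOVA over the four contrast-activation conditions
#'
#' Compares the four reliability conditions (instruction x segmentation
#' mode) of the contrast-activation measure.  Emits both a one-way
#' repeated-measures ANOVA over the four levels and the 2 x 2
#' (instruction x mode) decomposition; a non-significant result indicates
#' the quadrant and ring segment maps discriminate stimulus locations
#' equally well.
#'
#' @param contrasts data.frame with columns \code{subject},
#'   \code{instruction}, \code{mode}, \code{value} (one row per subject x
#'   condition).
#' @return list with \code{oneway} and \code{factorial} effect tables as
#'   returned by [rmAnova()].
#' @export
contrastActivationAnova <- function(contrasts) {
  contrasts$condition <- interaction(contrasts$instruction, contrasts$mode)
  list(oneway = rmAnova(contrasts, dv = "value", subject = "subject",
                        within = "condition"),
       factorial = rmAnova(contrasts, dv = "value", subject = "subject",
                           within = c("instruction", "mode")))
}
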