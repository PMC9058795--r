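## Posterior summary utilities: equal-tailed credible intervals, probability
## of direction, covariance-to-correlation transforms, variance contrasts.

#' Equal-tailed credible interval
#'
#' Quantile interval at the given level, using linear-interpolation (type 7)
#' quantiles.
#'
#' @param samples posterior draws (at least 100).
#' @param level interval mass (default 0.95).
#' @return named numeric vector \code{c(low, high)}.
#' @export
credibleInterval <- function(samples, level = 0.95) {
  if (length(samples) < 100)
    stop("credible intervals need at least 100 posterior samples")
  a <- (1 - level) / 2
  ci <- unname(quantile(samples, c(a, 1 - a), type = 7, names = FALSE))
  c(low = ci[1], high = ci[2])
}

#' Probability of direction
#'
#' Proportion of posterior draws sharing the sign of the posterior median,
#' lying in [0.5, 1]; draws exactly at zero are split evenly between signs.
#' Also returns the two-sided p-value analogue \code{2 * (1 - pd)}.
#'
#' @param samples posterior draws.
#' @return list with \code{pd} and \code{pTwoSided}.
#' @export
probabilityOfDirection <- function(samples) {
  if (length(samples) == 0) stop("no posterior samples")
  n <- length(samples)
  pos <- sum(samples > 0); neg <- sum(samples < 0)
  zero <- n - pos - neg
  med <- median(samples)
  pd <- if (med > 0) (pos + zero / 2) / n
        else if (med < 0) (neg + zero / 2) / n
        else (max(pos, neg) + zero / 2) / n
  pd <- min(max(pd, 0.5), 1)
  list(pd = pd, pTwoSided = 2 * (1 - pd))
}

#' Summarise one posterior sample vector
#'
#' @param samples posterior draws.
#' @param label row label.
#' @param level credible level.
#' @return one-row data.frame: label, estimate (posterior mean), ciLow,
#'   ciHigh, pd, pTwoSided, significant (CI excludes 0).
#' @export
summarizeSamples <- function(samples, label = "", level = 0.95) {
  ci <- credibleInterval(samples, level)
  pd <- probabilityOfDirection(samples)
  data.frame(label = label, estimate = mean(samples),
             ciLow = ci["low"], ciHigh = ci["high"],
             pd = pd$pd, pTwoSided = pd$pTwoSided,
             significant = ci["low"] > 0 | ci["high"] < 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transform covariance draws to correlation draws
#'
#' Per aligned draw, \code{r = cov / sqrt(varA * varB)}.  Draws with a
#' non-positive variance are dropped and counted.
#'
#' @param covDraws,varADraws,varBDraws aligned posterior draws.
#' @param level credible level for the summary.
#' @return list with \code{r} (correlation draws), \code{summary} (from
#'   [summarizeSamples()]) and \code{nDropped}.
#' @export
covToCorrelation <- function(covDraws, varADraws, varBDraws, level = 0.95) {
  n <- length(covDraws)
  if (length(varADraws) != n || length(varBDraws) != n)
    stop("draw vectors must be aligned by iteration")
  ok <- varADraws > 0 & varBDraws > 0
  r <- covDraws[ok] / sqrt(varADraws[ok] * varBDraws[ok])
  list(r = r, summary = summarizeSamples(r, "correlation", level),
       nDropped = sum(!ok))
}

#' Posterior contrast between two variance components
#'
#' Per-draw difference A - B summarised with its credible interval and
#' probability of direction; the published analyses used this to compare
#' random intercept/slope variances among contexts and traits, since variance
#' CIs themselves cannot cross zero.
#'
#' @param samplesA,samplesB aligned posterior draws.
#' @param label row label.
#' @param level credible level.
#' @return one-row data.frame as in [summarizeSamples()].
#' @export
varianceContrast <- function(samplesA, samplesB, label = "A-B", level = 0.95) {
  if (length(samplesA) != length(samplesB))
    stop("draw vectors must have equal length")
  summarizeSamples(samplesA - samplesB, label, level)
}

#' Posterior mass below a negligible-variance threshold
#'
#' A reproducible proxy for visual inspection of a variance posterior:
#' the fraction of draws below \code{threshold} (default 0.01 on the
#' z-scale).
#'
#' @param samples variance draws.
#' @param threshold negligible-variance threshold.
#' @return fraction in [0, 1].
#' @export
belowThresholdMass <- function(samples, threshold = 0.01)
  mean(samples < threshold)

#' Fixed-effect summary table
#'
#' One row per fixed-effect coefficient, pooling all chains.
#'
#' @param fit a [PosteriorDraws-class].
#' @param level credible level.
#' @return data.frame mirroring a results-table layout: label, estimate,
#'   ciLow, ciHigh, pd, pTwoSided, significant.
#' @export
summarizeFixedEffects <- function(fit, level = 0.95) {
  b <- betaDraws(fit)
  out <- do.call(rbind, lapply(colnames(b), function(cn)
    summarizeSamples(b[, cn], cn, level)))
  rownames(out) <- NULL
  out
}

#' Variance-component summary table
#'
#' Summarises every distinct element of each random-effect covariance block
#' and of the residual covariance.  For diagonal elements (variances), whose
#' credible intervals cannot cross zero, the significance flag is NA and the
#' posterior mass below the negligible-variance threshold is reported
#' instead.
#'
#' @param fit a [PosteriorDraws-class].
#' @param level credible level.
#' @param threshold negligible-variance threshold for diagonal elements.
#' @return data.frame with one row per (co)variance element.
#' @export
summarizeVarianceComponents <- function(fit, level = 0.95, threshold = 0.01) {
  comps <- c(names(fit@chains[[1]]$G), "resid")
  rows <- list()
  for (comp in comps) {
    arr <- varianceDraws(fit, comp)
    en <- dimnames(arr)[[2]]
    d <- dim(arr)[2]
    for (i in seq_len(d)) for (j in i:d) {
      s <- summarizeSamples(arr[, i, j],
                            sprintf("%s[%s,%s]", comp, en[i], en[j]), level)
      if (i == j) {
        s$significant <- NA
        s$massBelowThreshold <- belowThresholdMass(arr[, i, j], threshold)
      } else {
        s$massBelowThreshold <- NA_real_
      }
      rows[[length(rows) + 1L]] <- s
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
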