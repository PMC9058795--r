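#' Construct generator ground truth
#'
#' @param traits trait names (1 or 2), e.g. \code{c("SL", "MF")}.
#' @param beta fixed-effect matrix (traits x terms); see
#'   [TrueParameters-class] for the term order.
#' @param G named list of per-context covariance matrices of individual
#'   reaction-norm deviations.
#' @param Vyear,Rresid year and residual covariance across traits.
#' @param repeatNoiseSd sd of between-recording drift in individual slopes.
#' @return a [TrueParameters-class] object.
#' @export
trueParameters <- function(traits, beta, G, Vyear, Rresid, repeatNoiseSd = 0) {
  beta <- as.matrix(beta)
  rownames(beta) <- traits
  colnames(beta) <- .BETA_TERMS
  new("TrueParameters", traits = traits, beta = beta, G = G,
      Vyear = as.matrix(Vyear), Rresid = as.matrix(Rresid),
      repeatNoiseSd = repeatNoiseSd)
}

## Per-context covariance of individual deviations, built from standard
## deviations and a sparse set of correlations, effect order
## (intercept, order-slope, position-slope) within each trait.
.make_G <- function(sds, cors = list()) {
  d <- length(sds)
  Rho <- diag(d)
  for (cr in cors) {
    Rho[cr[[1]], cr[[2]]] <- Rho[cr[[2]], cr[[1]]] <- cr[[3]]
  }
  ev <- eigen(Rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) stop("default correlation structure not positive definite")
  diag(sds) %*% Rho %*% diag(sds)
}

#' Default ground truth emulating the collared flycatcher study
#'
#' Fixed effects default to the published population-level estimates for song
#' length (SL) and maximum frequency (MF) (or, for \code{"complexity"}, the
#' univariate complexity model).  The random-effect covariance structure is a
#' realistic synthetic choice: among-individual variance in order- and
#' position-slopes concentrated in the male-stimulus and no-stimulus contexts,
#' with negative correlations between order- and position-slopes in the male
#' context mirroring the reported trade-offs.
#'
#' @param traits \code{c("SL", "MF")} (default) or \code{"complexity"}.
#' @param repeatNoiseSd between-recording slope drift sd (default 0: slopes
#'   are perfectly repeatable across recordings).
#' @return a [TrueParameters-class] object.
#' @export
defaultTrueParameters <- function(traits = c("SL", "MF"), repeatNoiseSd = 0) {
  if (identical(traits, c("SL", "MF"))) {
    beta <- rbind(
      SL = c(0, 0.052, 0.034, 0.044, 0.047, 0.067, 0.066, 0.285, 0.273),
      MF = c(0, 0.008, 0.011, -0.028, -0.014, 0.070, 0.014, 0.379, 0.060))
    colnames(beta) <- .BETA_TERMS
    sds_m <- sqrt(c(0.25, 0.15, 0.10, 0.25, 0.15, 0.08))
    # indices: 1 SL int, 2 SL order, 3 SL pos, 4 MF int, 5 MF order, 6 MF pos
    G <- list(
      male = .make_G(sds_m, list(
        list(1L, 2L, -0.3), list(2L, 3L, -0.6), list(3L, 5L, -0.6),
        list(4L, 5L, -0.3), list(1L, 4L, 0.35))),
      female = .make_G(sqrt(c(0.25, 0.05, 0.05, 0.25, 0.05, 0.05)),
                       list(list(1L, 4L, 0.35))),
      none = .make_G(sqrt(c(0.25, 0.12, 0.06, 0.25, 0.08, 0.05)),
                     list(list(1L, 2L, -0.3), list(1L, 4L, 0.35))))
    Vyear <- .make_G(sqrt(c(0.05, 0.05)), list(list(1L, 2L, 0.3)))
    Rresid <- .make_G(sqrt(c(0.60, 0.65)), list(list(1L, 2L, 0.3)))
  } else if (identical(traits, "complexity")) {
    beta <- rbind(
      complexity = c(0, 0.043, -0.068, 0.024, 0.062, 0.040, -0.055, 0.078, -0.040))
    colnames(beta) <- .BETA_TERMS
    G <- list(male = .make_G(sqrt(c(0.20, 0.03, 0.03))),
              female = .make_G(sqrt(c(0.20, 0.03, 0.03))),
              none = .make_G(sqrt(c(0.20, 0.03, 0.03))))
    Vyear <- matrix(0.05)
    Rresid <- matrix(0.70)
  } else {
    stop("defaults exist for traits c('SL','MF') or 'complexity'")
  }
  trueParameters(traits, beta, G, Vyear, Rresid, repeatNoiseSd)
}

#' Construct a simulation configuration
#'
#' Defaults emulate the field study: 185 focal males, context frequencies
#' proportional to the reported 85 / 45 / 66 individuals per context, 9--126
#' songs per recording, 12 study years, about 20 percent of individuals with a
#' second recording (65 percent of those in the same context), and 15 percent
#' of songs with an unobserved singing position.
#'
#' @param nIndividuals,contextProbs,songsPerRecording,positionShape
#'   see [SimulationConfig-class].
#' @param missingPositionProb,nYears,propRepeated,propRepeatedSameContext,seed
#'   see [SimulationConfig-class].
#' @return a [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nIndividuals = 185,
                             contextProbs = c(male = 85, female = 45, none = 66) / 196,
                             songsPerRecording = c(9, 126),
                             positionShape = c(2, 2),
                             missingPositionProb = 0.15,
                             nYears = 12,
                             propRepeated = 0.2,
                             propRepeatedSameContext = 0.65,
                             seed = 1) {
  if (is.null(names(contextProbs))) names(contextProbs) <- .CONTEXTS
  new("SimulationConfig",
      nIndividuals = as.integer(nIndividuals),
      contextProbs = contextProbs / sum(contextProbs),
      songsPerRecording = as.integer(songsPerRecording),
      positionShape = as.numeric(positionShape),
      missingPositionProb = missingPositionProb,
      nYears = as.integer(nYears),
      propRepeated = propRepeated,
      propRepeatedSameContext = propRepeatedSameContext,
      seed = as.integer(seed))
}

#' Construct a model specification
#'
#' @param responses one or two response column names.
#' @param fixedTerms fixed-effect terms; defaults to the full published model
#'   (date, age, order in interaction with context, singing position).
#' @param randomEffects individual-level random terms estimated separately per
#'   context.
#' @param yearRandom include a year random intercept.
#' @param priorFamily,priorScale,priorNu,alphaVar prior settings; see
#'   [ModelSpec-class].
#' @return a [ModelSpec-class] object.
#' @export
modelSpec <- function(responses,
                      fixedTerms = c("date", "age", "order", "position",
                                     "context", "order_context"),
                      randomEffects = c("intercept", "order", "position"),
                      yearRandom = TRUE,
                      priorFamily = c("parameter_expanded", "inverse_wishart"),
                      priorScale = 0.002, priorNu = NA_real_, alphaVar = 1000) {
  new("ModelSpec", responses = responses, fixedTerms = fixedTerms,
      randomEffects = randomEffects, yearRandom = yearRandom,
      priorFamily = match.arg(priorFamily), priorScale = priorScale,
      priorNu = priorNu, alphaVar = alphaVar)
}

#' Construct chain settings
#'
#' @param nIterations,burnIn,thin,nChains,seed see [ChainConfig-class].
#' @return a [ChainConfig-class] object.
#' @export
chainConfig <- function(nIterations, burnIn, thin, nChains = 2, seed = 1) {
  new("ChainConfig", nIterations = as.integer(nIterations),
      burnIn = as.integer(burnIn), thin = as.integer(thin),
      nChains = as.integer(nChains), seed = as.integer(seed))
}

#' Published single-chain MCMC settings
#'
#' 510,000 iterations, 10,000 burn-in, thinning interval 500, retaining
#' exactly 1000 draws.
#'
#' @param seed RNG seed.
#' @return a [ChainConfig-class] object.
#' @export
publishedChains <- function(seed = 1) chainConfig(510000, 10000, 500, nChains = 1, seed = seed)

#' Short default settings for automated runs
#'
#' Four shorter chains suitable for split-chain Gelman--Rubin diagnostics.
#'
#' @param nIterations,burnIn,thin,nChains,seed chain settings.
#' @return a [ChainConfig-class] object.
#' @export
fastChains <- function(nIterations = 6000, burnIn = 1000, thin = 5,
                       nChains = 4, seed = 1)
  chainConfig(nIterations, burnIn, thin, nChains = nChains, seed = seed)

#' @describeIn retainedSamples number of retained draws implied by chain
#'   settings: \code{floor((nIterations - burnIn) / thin)}.
#' @export
setMethod("retainedSamples", "ChainConfig", function(object)
  (object@nIterations - object@burnIn) %/% object@thin)

setMethod("show", "TrueParameters", function(object) {
  cat("TrueParameters:", paste(object@traits, collapse = " + "),
      sprintf("| %d-dim context blocks | repeatNoiseSd = %g\n",
              nrow(object@G[[1]]), object@repeatNoiseSd))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d individuals, %d-%d songs/recording, %d years, %.0f%% repeated\n",
              object@nIndividuals, object@songsPerRecording[1],
              object@songsPerRecording[2], object@nYears,
              100 * object@propRepeated))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", paste(object@responses, collapse = " + "),
      "| random:", paste(object@randomEffects, collapse = "+"),
      "| prior:", object@priorFamily, "\n")
})

setMethod("show", "ChainConfig", function(object) {
  cat(sprintf("ChainConfig: %d chains x %d iterations (burn-in %d, thin %d) -> %d retained\n",
              object@nChains, object@nIterations, object@burnIn, object@thin,
              retainedSamples(object)))
})

setMethod("show", "DesignMatrices", function(object) {
  cat(sprintf("DesignMatrices: %d rows x %d traits, %d fixed + %d random columns, %d blocks\n",
              nrow(object@Y), ncol(object@Y), object@pFixed,
              ncol(object@W) - object@pFixed, length(object@blocks)))
  if (sum(object@rowsDropped))
    cat("  rows dropped:", paste(names(object@rowsDropped), object@rowsDropped,
                                 sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %d chains x %d retained draws (%s prior)\n",
              length(object@chains), nRetained(object), object@priorFamily))
})

setMethod("show", "RepeatabilityResult", function(object) {
  cat(sprintf("Repeatability of %s ~ %s slope (%s context): R = %.3f (%.3f, %.3f), %d individuals\n",
              object@trait, object@gradient, object@context, object@Rmean,
              object@ciLow, object@ciHigh, object@nIndividuals))
})
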