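#' @import methods
#' @importFrom stats quantile median rnorm rbinom runif rbeta sd var setNames
#'   complete.cases lm coef qnorm
#' @importFrom utils read.csv write.csv head
#' @useDynLib songplast, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## canonical labels used throughout
.CONTEXTS <- c("male", "female", "none")
.BETA_TERMS <- c("intercept", "date", "age", "order", "position",
                 "context_female", "context_none",
                 "order_context_female", "order_context_none")
.GRADIENTS <- c("order", "position")

.check_cov <- function(M, what) {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    return(sprintf("%s must be a square matrix", what))
  if (max(abs(M - t(M))) > 1e-8)
    return(sprintf("%s must be symmetric", what))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    return(sprintf("%s must be positive semi-definite (min eigenvalue %.3g)",
                   what, min(ev)))
  NULL
}

#' Ground-truth parameters of the song-plasticity generator
#'
#' Houses the fixed-effect coefficients (on the z-scale of each trait), the
#' context-specific covariance matrices of individual reaction-norm deviations
#' (intercept, order-slope, position-slope per trait), the year-effect and
#' residual (co)variances across traits, and the standard deviation of
#' between-recording drift in individual slopes used in repeatability
#' scenarios.
#'
#' @slot traits character vector of trait names (1 or 2).
#' @slot beta matrix of fixed effects, rows = traits, columns = model terms.
#' @slot G named list of per-context covariance matrices (dimension
#'   \code{3 * length(traits)}), effect order: intercept, order-slope,
#'   position-slope within each trait.
#' @slot Vyear year-effect covariance across traits.
#' @slot Rresid residual covariance across traits.
#' @slot repeatNoiseSd standard deviation of recording-level slope drift.
#' @export
setClass("TrueParameters",
  representation(traits = "character", beta = "matrix", G = "list",
                 Vyear = "matrix", Rresid = "matrix",
                 repeatNoiseSd = "numeric"))

setValidity("TrueParameters", function(object) {
  T <- length(object@traits)
  msgs <- character()
  if (T < 1 || T > 2) msgs <- c(msgs, "1 or 2 traits supported")
  if (anyDuplicated(object@traits)) msgs <- c(msgs, "trait names must be unique")
  if (!identical(rownames(object@beta), object@traits))
    msgs <- c(msgs, "beta rows must be named by trait")
  if (!identical(colnames(object@beta), .BETA_TERMS))
    msgs <- c(msgs, sprintf("beta columns must be: %s",
                            paste(.BETA_TERMS, collapse = ", ")))
  if (!all(.CONTEXTS %in% names(object@G)))
    msgs <- c(msgs, "G must be a list with entries male, female, none")
  for (ctx in intersect(names(object@G), .CONTEXTS)) {
    m <- .check_cov(object@G[[ctx]], paste0("G[", ctx, "]"))
    if (!is.null(m)) msgs <- c(msgs, m)
    else if (nrow(object@G[[ctx]]) != 3L * T)
      msgs <- c(msgs, sprintf("G[%s] must be %d x %d", ctx, 3 * T, 3 * T))
  }
  for (nm in c("Vyear", "Rresid")) {
    m <- .check_cov(slot(object, nm), nm)
    if (!is.null(m)) msgs <- c(msgs, m)
    else if (nrow(slot(object, nm)) != T)
      msgs <- c(msgs, sprintf("%s must be %d x %d", nm, T, T))
  }
  if (length(object@repeatNoiseSd) != 1L || object@repeatNoiseSd < 0)
    msgs <- c(msgs, "repeatNoiseSd must be a single non-negative number")
  if (length(msgs)) msgs else TRUE
})

#' Configuration of the synthetic song-recording study
#'
#' @slot nIndividuals number of focal individuals.
#' @slot contextProbs probabilities of the male / female / no-stimulus
#'   contexts (sum to 1).
#' @slot songsPerRecording integer range (min, max) of songs per recording.
#' @slot positionShape shape parameters of the Beta distribution generating
#'   singing positions (rescaled to 0--100 percent of vegetation height).
#' @slot missingPositionProb fraction of songs whose singing position is
#'   unobserved.
#' @slot nYears number of study years.
#' @slot propRepeated fraction of individuals with a second recording.
#' @slot propRepeatedSameContext probability that the second recording is made
#'   in the same social context as the first.
#' @slot seed default RNG seed for the generator.
#' @export
setClass("SimulationConfig",
  representation(nIndividuals = "integer", contextProbs = "numeric",
                 songsPerRecording = "integer", positionShape = "numeric",
                 missingPositionProb = "numeric", nYears = "integer",
                 propRepeated = "numeric", propRepeatedSameContext = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nIndividuals < 1L) msgs <- c(msgs, "nIndividuals must be >= 1")
  if (length(object@contextProbs) != 3L ||
      !identical(names(object@contextProbs), .CONTEXTS) ||
      any(object@contextProbs < 0) || any(object@contextProbs > 1) ||
      abs(sum(object@contextProbs) - 1) > 1e-8)
    msgs <- c(msgs, "contextProbs must be a named 3-vector (male, female, none) summing to 1")
  if (length(object@songsPerRecording) != 2L ||
      object@songsPerRecording[1] < 1L ||
      object@songsPerRecording[2] < object@songsPerRecording[1])
    msgs <- c(msgs, "songsPerRecording must be an increasing range with min >= 1")
  if (any(object@positionShape <= 0)) msgs <- c(msgs, "positionShape must be positive")
  for (nm in c("missingPositionProb", "propRepeated", "propRepeatedSameContext")) {
    v <- slot(object, nm)
    if (length(v) != 1L || v < 0 || v > 1)
      msgs <- c(msgs, sprintf("%s must be a probability in [0, 1]", nm))
  }
  if (object@nYears < 1L) msgs <- c(msgs, "nYears must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Declarative description of a random-regression model
#'
#' @slot responses one or two trait/column names to model jointly.
#' @slot fixedTerms fixed-effect terms (subset of date, age, order, position,
#'   context, order_context); the intercept is always included and context
#'   terms are dropped automatically when a single context is present.
#' @slot randomEffects individual-level random terms per context: subset of
#'   intercept, order, position.
#' @slot yearRandom include a year random-intercept block.
#' @slot priorFamily "parameter_expanded" or "inverse_wishart".
#' @slot priorScale scalar multiplier of the identity prior scale matrix
#'   (default 0.002, the weakly-informative convention).
#' @slot priorNu prior degrees of belief per block (NA = block dimension
#'   minus 0.998, keeping every conditional update proper).
#' @slot alphaVar prior variance of the working scales under parameter
#'   expansion.
#' @export
setClass("ModelSpec",
  representation(responses = "character", fixedTerms = "character",
                 randomEffects = "character", yearRandom = "logical",
                 priorFamily = "character", priorScale = "numeric",
                 priorNu = "numeric", alphaVar = "numeric"))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (length(object@responses) < 1L || length(object@responses) > 2L)
    msgs <- c(msgs, "1 or 2 responses supported")
  bad <- setdiff(object@fixedTerms,
                 c("date", "age", "order", "position", "context", "order_context"))
  if (length(bad)) msgs <- c(msgs, paste("unknown fixed terms:", paste(bad, collapse = ", ")))
  bad <- setdiff(object@randomEffects, c("intercept", "order", "position"))
  if (length(bad)) msgs <- c(msgs, paste("unknown random effects:", paste(bad, collapse = ", ")))
  if (!"intercept" %in% object@randomEffects && length(object@randomEffects))
    msgs <- c(msgs, "individual random structure must include the intercept")
  if (!object@priorFamily %in% c("parameter_expanded", "inverse_wishart"))
    msgs <- c(msgs, "priorFamily must be parameter_expanded or inverse_wishart")
  if (object@priorScale <= 0) msgs <- c(msgs, "priorScale must be positive")
  if (object@alphaVar <= 0) msgs <- c(msgs, "alphaVar must be positive")
  if (length(msgs)) msgs else TRUE
})

#' MCMC chain settings
#'
#' @slot nIterations total Gibbs iterations per chain.
#' @slot burnIn discarded initial iterations.
#' @slot thin thinning interval.
#' @slot nChains number of independent chains.
#' @slot seed base RNG seed; chain c uses seed + c - 1.
#' @export
setClass("ChainConfig",
  representation(nIterations = "integer", burnIn = "integer", thin = "integer",
                 nChains = "integer", seed = "integer"))

setValidity("ChainConfig", function(object) {
  msgs <- character()
  if (object@burnIn >= object@nIterations)
    msgs <- c(msgs, "burnIn must be smaller than nIterations")
  if (object@burnIn < 0L) msgs <- c(msgs, "burnIn must be non-negative")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (object@nChains < 1L) msgs <- c(msgs, "nChains must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Compiled design structures for the Gibbs sampler
#'
#' Produced by [buildDesign()] (or assembled directly with [designMatrices()]
#' for non-standard models).  Holds the z-scaled response matrix, the shared
#' fixed + random design matrix, per-block bookkeeping (which design columns
#' and observation rows belong to each group level) and the record of rows
#' dropped during listwise deletion.
#'
#' @slot Y n x T response matrix on the z-scale.
#' @slot W n x P design matrix (fixed-effect columns first).
#' @slot pFixed number of fixed-effect columns.
#' @slot fixedNames names of the fixed-effect columns.
#' @slot blocks list of random-effect block descriptors.
#' @slot rowsDropped named integer vector of listwise deletions by reason.
#' @slot index data.frame mapping retained rows to individual / recording /
#'   year / context.
#' @slot spec the [ModelSpec-class] the design was built for.
#' @export
setClass("DesignMatrices",
  representation(Y = "matrix", W = "matrix", pFixed = "integer",
                 fixedNames = "character", blocks = "list",
                 rowsDropped = "integer", index = "data.frame",
                 spec = "ModelSpec"))

setValidity("DesignMatrices", function(object) {
  msgs <- character()
  if (nrow(object@Y) != nrow(object@W))
    msgs <- c(msgs, "Y and W must have the same number of rows")
  if (object@pFixed > ncol(object@W))
    msgs <- c(msgs, "pFixed exceeds the number of design columns")
  if (anyNA(object@Y) || anyNA(object@W))
    msgs <- c(msgs, "design must be complete-case (no missing values)")
  for (blk in object@blocks) {
    if (!all(c("name", "cols", "rows", "levels", "effectNames") %in% names(blk)))
      msgs <- c(msgs, "malformed random-effect block descriptor")
    else if (length(blk$cols) && max(blk$cols) > ncol(object@W))
      msgs <- c(msgs, sprintf("block %s references missing design columns", blk$name))
  }
  if (length(msgs)) msgs else TRUE
})

#' Retained posterior draws of a random-regression fit
#'
#' @slot chains per-chain lists with elements beta (draws x coefficients),
#'   G (list of draws x dim x dim arrays per random block), R (draws x T x T
#'   array), u (individual-level effect arrays per block), loglik.
#' @slot design the [DesignMatrices-class] that was fitted.
#' @slot config the [ChainConfig-class] used.
#' @slot priorFamily prior family actually used.
#' @export
setClass("PosteriorDraws",
  representation(chains = "list", design = "DesignMatrices",
                 config = "ChainConfig", priorFamily = "character"))

#' Repeatability of reaction-norm slopes
#'
#' @slot trait,gradient,context the slope the estimate refers to.
#' @slot draws posterior draws of R = V_individual / (V_individual + V_residual).
#' @slot Rmean posterior mean.
#' @slot ciLow,ciHigh 95 percent credible bounds.
#' @slot nIndividuals,nSongs sample sizes entering stage 1.
#' @export
setClass("RepeatabilityResult",
  representation(trait = "character", gradient = "character",
                 context = "character", draws = "numeric", Rmean = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 nIndividuals = "integer", nSongs = "integer"))

setValidity("RepeatabilityResult", function(object) {
  if (any(object@draws < 0 | object@draws > 1))
    return("repeatability draws must lie in [0, 1]")
  TRUE
})
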