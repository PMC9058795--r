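#' Number of retained posterior draws
#'
#' @param object a [ChainConfig-class] or [PosteriorDraws-class].
#' @return integer count of retained draws (per chain).
#' @export
setGeneric("retainedSamples", function(object) standardGeneric("retainedSamples"))

#' Fixed-effect draws
#'
#' @param object a [PosteriorDraws-class].
#' @param chain chain index, or NULL to pool all chains.
#' @return matrix of draws x named coefficients.
#' @export
setGeneric("betaDraws", function(object, chain = NULL) standardGeneric("betaDraws"))

#' (Co)variance-component draws
#'
#' @param object a [PosteriorDraws-class].
#' @param component block name (e.g. \code{"individual:male"}, \code{"year"})
#'   or \code{"resid"}.
#' @param chain chain index, or NULL to pool all chains.
#' @return 3-dimensional array draws x dim x dim with effect dimnames.
#' @export
setGeneric("varianceDraws", function(object, component, chain = NULL)
  standardGeneric("varianceDraws"))

#' Individual-level effect draws
#'
#' @param object a [PosteriorDraws-class].
#' @param component random-effect block name.
#' @param chain chain index, or NULL to pool all chains.
#' @return array draws x levels x effects.
#' @export
setGeneric("individualDraws", function(object, component, chain = NULL)
  standardGeneric("individualDraws"))

#' Number of retained draws per chain of a fit
#'
#' @param object a [PosteriorDraws-class].
#' @return integer.
#' @export
setGeneric("nRetained", function(object) standardGeneric("nRetained"))

#' Gelman--Rubin convergence diagnostic
#'
#' Rank-normalised split potential-scale-reduction factor, computed per scalar
#' parameter across at least two chains.  Values close to 1 indicate that the
#' chains are consistent with having converged to the same distribution.
#'
#' @param object a [PosteriorDraws-class] with at least two chains, or a
#'   numeric matrix with one column per chain.
#' @param ... unused.
#' @return named numeric vector of split-Rhat values.
#' @export
setGeneric("gelmanRubin", function(object, ...) standardGeneric("gelmanRubin"))
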