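## R-side orchestration of the C++ blocked Gibbs sampler.

.bind_first <- function(xs) {
  if (length(xs) == 1L) return(xs[[1]])
  if (is.matrix(xs[[1]])) return(do.call(rbind, xs))
  if (is.array(xs[[1]])) {
    d <- dim(xs[[1]]); d[1] <- sum(vapply(xs, function(x) dim(x)[1], 0))
    out <- array(NA_real_, d, dimnames = dimnames(xs[[1]]))
    at <- 0L
    for (x in xs) {
      out[at + seq_len(dim(x)[1]), , ] <- x
      at <- at + dim(x)[1]
    }
    return(out)
  }
  unlist(xs)
}

#' Fit a random-regression model by blocked Gibbs sampling
#'
#' Runs the sampler on a compiled design: (i) a joint multivariate-normal
#' update of all fixed and random location effects given the current
#' covariances, (ii) inverse-Wishart conditional updates of every
#' random-effect covariance block and the residual covariance, and (iii) under
#' the parameter-expanded prior family, an additional Gaussian update of
#' redundant multiplicative working scales applied to each random block, which
#' improves mixing for variance components near zero.  Chains are independent
#' and differ only by seed.
#'
#' @param design a [DesignMatrices-class] from [buildDesign()] or
#'   [designMatrices()].
#' @param chains a [ChainConfig-class]; see [publishedChains()] and
#'   [fastChains()].
#' @param priorFamily override of the design spec's prior family.
#' @param betaVar prior variance of each fixed effect (effectively flat on
#'   the z-scale).
#' @param residNu,residScale residual inverse-Wishart prior (defaults to the
#'   weakly-informative convention: df = nTraits - 0.998, scale 0.002 I).
#' @param Rinit initial residual covariance (identity default).
#' @param updateResid set FALSE to hold the residual covariance fixed at
#'   \code{Rinit} (used by closed-form oracle checks).
#' @param saveU retain individual-level effect draws (needed for slope
#'   extraction).
#' @return a [PosteriorDraws-class].
#' @export
gibbsSample <- function(design, chains = fastChains(),
                        priorFamily = NULL, betaVar = 1e8,
                        residNu = NULL, residScale = NULL, Rinit = NULL,
                        updateResid = TRUE, saveU = TRUE) {
  validObject(design); validObject(chains)
  spec <- design@spec
  if (is.null(priorFamily)) priorFamily <- spec@priorFamily
  priorFamily <- match.arg(priorFamily,
                           c("parameter_expanded", "inverse_wishart"))
  Tt <- ncol(design@Y)
  traits <- colnames(design@Y)
  if (retainedSamples(chains) < 1)
    stop("chain settings retain no draws")
  px <- priorFamily == "parameter_expanded"

  cpp_blocks <- lapply(design@blocks, function(blk) {
    qT <- ncol(blk$cols) * Tt
    nu0 <- if (is.na(spec@priorNu)) qT - 0.998 else spec@priorNu
    list(cols = blk$cols, rows = blk$rows, nu0 = nu0,
         S0 = spec@priorScale * diag(qT), px = px, alphaV = spec@alphaVar)
  })
  if (is.null(residNu)) residNu <- Tt - 0.998
  if (is.null(residScale)) residScale <- 0.002 * diag(Tt)
  if (is.null(Rinit)) Rinit <- diag(Tt)

  out <- vector("list", chains@nChains)
  for (ch in seq_len(chains@nChains)) {
    set.seed(chains@seed + ch - 1L)
    raw <- gibbs_lmm_cpp(design@Y, design@W, design@pFixed, cpp_blocks,
                         betaVar, residNu, as.matrix(residScale),
                         as.matrix(Rinit), updateResid,
                         chains@nIterations, chains@burnIn, chains@thin,
                         saveU)
    nret <- raw$retained
    beta <- raw$beta
    ## C++ stores trait-major with coefficient fastest
    colnames(beta) <- as.vector(vapply(
      traits, function(tr) paste(tr, design@fixedNames, sep = ":"),
      character(design@pFixed)))
    Rarr <- array(raw$R, dim = c(nret, Tt, Tt),
                  dimnames = list(NULL, traits, traits))
    Gs <- list(); Us <- list()
    for (b in seq_along(design@blocks)) {
      blk <- design@blocks[[b]]
      qT <- ncol(blk$cols) * Tt
      en <- .full_effect_names(traits, blk$effectNames)
      Gs[[blk$name]] <- array(raw$G[[b]], dim = c(nret, qT, qT),
                              dimnames = list(NULL, en, en))
      if (saveU)
        Us[[blk$name]] <- array(raw$u[[b]],
                                dim = c(nret, length(blk$levels), qT),
                                dimnames = list(NULL, blk$levels, en))
    }
    out[[ch]] <- list(beta = beta, R = Rarr, G = Gs, u = Us,
                      loglik = as.vector(raw$loglik))
  }
  new("PosteriorDraws", chains = out, design = design, config = chains,
      priorFamily = priorFamily)
}

#' @describeIn retainedSamples retained draws per chain of a fit.
#' @export
setMethod("retainedSamples", "PosteriorDraws", function(object)
  nrow(object@chains[[1]]$beta))

#' @rdname nRetained
#' @export
setMethod("nRetained", "PosteriorDraws", function(object)
  nrow(object@chains[[1]]$beta))

.pick_chains <- function(object, chain) {
  if (is.null(chain)) object@chains else object@chains[chain]
}

#' @rdname betaDraws
#' @export
setMethod("betaDraws", "PosteriorDraws", function(object, chain = NULL)
  .bind_first(lapply(.pick_chains(object, chain), `[[`, "beta")))

#' @rdname varianceDraws
#' @export
setMethod("varianceDraws", "PosteriorDraws",
  function(object, component, chain = NULL) {
    chs <- .pick_chains(object, chain)
    if (identical(component, "resid"))
      return(.bind_first(lapply(chs, `[[`, "R")))
    if (!component %in% names(chs[[1]]$G))
      stop("unknown component '", component, "'; available: ",
           paste(c(names(chs[[1]]$G), "resid"), collapse = ", "))
    .bind_first(lapply(chs, function(ch) ch$G[[component]]))
  })

#' @rdname individualDraws
#' @export
setMethod("individualDraws", "PosteriorDraws",
  function(object, component, chain = NULL) {
    chs <- .pick_chains(object, chain)
    if (!length(chs[[1]]$u)) stop("fit was run with saveU = FALSE")
    if (!component %in% names(chs[[1]]$u))
      stop("unknown component '", component, "'")
    .bind_first(lapply(chs, function(ch) ch$u[[component]]))
  })

## ---- convergence diagnostics ----

## rank-normalised split potential-scale-reduction factor
.split_rhat <- function(m) {
  m <- as.matrix(m)
  n2 <- nrow(m) %/% 2
  if (n2 < 2) return(NA_real_)
  sm <- do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[seq_len(n2), j], m[nrow(m) - n2 + seq_len(n2), j])))
  if (stats::var(as.vector(sm)) == 0) return(1)
  r <- matrix(rank(sm, ties.method = "average"), nrow(sm))
  z <- qnorm((r - 3 / 8) / (length(sm) + 1 / 4))
  Wv <- mean(apply(z, 2, stats::var))
  Bv <- n2 * stats::var(colMeans(z))
  if (Wv == 0) return(1)
  sqrt(((n2 - 1) / n2 * Wv + Bv / n2) / Wv)
}

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "matrix", function(object, ...) {
  if (ncol(object) < 2)
    stop("Gelman-Rubin diagnostics need at least 2 chains (nChains >= 2)")
  .split_rhat(object)
})

#' @rdname gelmanRubin
#' @export
setMethod("gelmanRubin", "PosteriorDraws", function(object, ...) {
  if (length(object@chains) < 2)
    stop("Gelman-Rubin diagnostics need at least 2 chains (nChains >= 2)")
  per_param <- function(extract) {
    vapply(seq_len(ncol(extract(object@chains[[1]]))), function(j)
      .split_rhat(vapply(object@chains, function(ch) extract(ch)[, j],
                         numeric(nrow(object@chains[[1]]$beta)))),
      numeric(1))
  }
  out <- per_param(function(ch) ch$beta)
  names(out) <- colnames(object@chains[[1]]$beta)
  for (comp in names(object@chains[[1]]$G)) {
    qT <- dim(object@chains[[1]]$G[[comp]])[2]
    en <- dimnames(object@chains[[1]]$G[[comp]])[[2]]
    for (i in seq_len(qT)) for (j in i:qT) {
      v <- vapply(object@chains, function(ch) ch$G[[comp]][, i, j],
                  numeric(nrow(object@chains[[1]]$beta)))
      out[sprintf("%s[%s,%s]", comp, en[i], en[j])] <- .split_rhat(v)
    }
  }
  Tt <- dim(object@chains[[1]]$R)[2]
  tn <- dimnames(object@chains[[1]]$R)[[2]]
  for (i in seq_len(Tt)) for (j in i:Tt) {
    v <- vapply(object@chains, function(ch) ch$R[, i, j],
                numeric(nrow(object@chains[[1]]$beta)))
    out[sprintf("resid[%s,%s]", tn[i], tn[j])] <- .split_rhat(v)
  }
  out
})
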