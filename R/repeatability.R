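## Two-step repeatability of reaction-norm slopes across repeated recordings.

#' Filter repeated recordings made in the same social context
#'
#' Keeps individuals with at least two recordings whose first two (by date)
#' share a social context; those two recordings are retained with
#' recording_order reassigned 1 and 2.
#'
#' @param recordings data.frame with individual_id, recording_id, date,
#'   context (one row per recording).
#' @return filtered recordings data.frame (possibly empty).
#' @export
filterRepeatedSameContext <- function(recordings) {
  recordings <- as.data.frame(recordings)
  out <- list()
  for (id in unique(recordings$individual_id)) {
    rr <- recordings[recordings$individual_id == id, , drop = FALSE]
    if (nrow(rr) < 2) next
    rr <- rr[order(rr$date, rr$recording_id), , drop = FALSE][1:2, ]
    if (rr$context[1] != rr$context[2]) next
    rr$recording_order <- 1:2
    out[[length(out) + 1L]] <- rr
  }
  if (!length(out)) return(recordings[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Extract per-individual slope draws from a fit
#'
#' Returns the full posterior draw matrix of every individual's random slope
#' for one (trait, gradient) combination from a fitted model.
#'
#' @param fit a [PosteriorDraws-class] fitted with \code{saveU = TRUE}.
#' @param trait response name.
#' @param gradient \code{"order"} or \code{"position"}.
#' @param context social context of the block (optional when the fit has a
#'   single individual block).
#' @return matrix draws x individuals (colnames = individual ids).
#' @export
extractSlopeDraws <- function(fit, trait, gradient = c("order", "position"),
                              context = NULL) {
  gradient <- match.arg(gradient)
  blocks <- Filter(function(b) b$type == "individual", fit@design@blocks)
  if (!length(blocks)) stop("fit has no individual random block")
  if (is.null(context)) {
    if (length(blocks) > 1)
      stop("fit has several context blocks; specify context")
    blk <- blocks[[1]]
  } else {
    nm <- paste0("individual:", context)
    hit <- vapply(blocks, function(b) b$name == nm, logical(1))
    if (!any(hit)) stop("no random block for context '", context, "'")
    blk <- blocks[[which(hit)]]
  }
  if (!gradient %in% blk$effectNames)
    stop("block has no random ", gradient, " slope")
  u <- individualDraws(fit, blk$name)
  key <- paste(trait, gradient, sep = ":")
  if (!key %in% dimnames(u)[[3]]) stop("no effect '", key, "' in block")
  u[, , key, drop = TRUE]
}

## stage-2 design: intercept + recording-order dummy + individual intercepts,
## for m individuals with `reps` stacked rows per individual-recording
.stage2_design <- function(ids, reps, priorFamily) {
  m <- length(ids)
  n <- 2L * m * reps
  W <- cbind(`(Intercept)` = rep(1, n),
             rec2 = rep(c(0, 1), each = m * reps),
             matrix(0, n, m))
  rows <- vector("list", m)
  cols <- matrix(0L, m, 1, dimnames = list(ids, "intercept"))
  for (j in seq_len(m)) {
    rj <- c((j - 1L) * reps + seq_len(reps),
            m * reps + (j - 1L) * reps + seq_len(reps))
    rows[[j]] <- rj
    W[rj, 2L + j] <- 1
    cols[j, 1] <- 2L + j
  }
  blk <- list(name = "individual", type = "individual", context = NA_character_,
              levels = ids, effectNames = "intercept", cols = cols, rows = rows)
  spec <- modelSpec("slope", fixedTerms = character(),
                    randomEffects = "intercept", yearRandom = FALSE,
                    priorFamily = priorFamily)
  list(W = W, blk = blk, spec = spec)
}

## one stage-2 Gibbs fit; returns draws of R = V_ind / (V_ind + V_res)
.stage2_fit <- function(y, d2, chains) {
  des <- designMatrices(matrix(y, dimnames = list(NULL, "slope")), d2$W, 2L,
                        blocks = list(d2$blk), spec = d2$spec)
  fit <- gibbsSample(des, chains, saveU = FALSE)
  vind <- varianceDraws(fit, "individual")[, 1, 1]
  vres <- varianceDraws(fit, "resid")[, 1, 1]
  vind / (vind + vres)
}

## moment-based one-way ICC with 2 measurements per individual, recording
## mean difference removed
.icc_moments <- function(y1, y2) {
  y2c <- y2 - mean(y2) + mean(y1)
  m <- length(y1)
  mi <- (y1 + y2c) / 2
  msb <- 2 * sum((mi - mean(mi))^2) / (m - 1)
  msw <- sum((y1 - mi)^2 + (y2c - mi)^2) / m
  vind <- max(0, (msb - msw) / 2)
  if (vind + msw <= 0) return(0)
  vind / (vind + msw)
}

#' Two-step repeatability of reaction-norm slopes
#'
#' Step 1 fits two random-regression models restricted to one social context
#' -- one on the first and one on the second recordings of the same birds --
#' with age, date, order and singing position as fixed effects and a random
#' intercept plus the target gradient slope for individual identity (and a
#' year random intercept when at least two years are present), then extracts
#' all retained posterior draws of each individual's slope.  Step 2 builds
#' univariate models with the individual slope estimates as the response,
#' recording order as a fixed factor and individual identity as a random
#' intercept, and reports the posterior of
#' \code{R = V_individual / (V_individual + V_residual)}.
#'
#' Three stage-2 estimators are available.  \code{"per_draw"} (default)
#' repeats the stage-2 model for every aligned pair of stage-1 posterior
#' samples -- a short Gibbs chain per sample, pooling all stage-2 posteriors
#' -- so that stage-1 uncertainty propagates into the credible interval.
#' \code{"stacked"} fits a single model on all draws stacked as rows; this is
#' deterministic and cheap but, because the stacked rows within an
#' individual-recording are correlated posterior draws, it allocates half of
#' the between-recording slope variance to the among-individual component and
#' therefore overstates R when slopes drift between recordings (the
#' discrepancy is visible by comparing the two methods).  \code{"moment"}
#' computes a moment-based one-way intraclass correlation per aligned draw
#' pair (fast, deterministic, no stage-2 MCMC).
#'
#' @param songs song table containing repeated recordings.
#' @param trait response name.
#' @param gradient \code{"order"} or \code{"position"}.
#' @param context social context to which the analysis is restricted.
#' @param chains1 stage-1 chain settings.
#' @param chains2 stage-2 chain settings (per draw under \code{"per_draw"};
#'   defaults there to a short 500-iteration chain retaining 20 draws).
#' @param priorFamily prior family for both stages.
#' @param includePosition keep singing position as a fixed effect in stage 1.
#' @param method stage-2 estimator (see Details).
#' @return a [RepeatabilityResult-class].
#' @export
slopeRepeatability <- function(songs, trait, gradient = "order",
                               context = "male",
                               chains1 = chainConfig(8000, 1000, 7, nChains = 1),
                               chains2 = NULL,
                               priorFamily = "parameter_expanded",
                               includePosition = TRUE,
                               method = c("per_draw", "stacked", "moment")) {
  method <- match.arg(method)
  songs <- as.data.frame(songs)
  recs <- unique(songs[, c("individual_id", "recording_id", "date", "context")])
  kept <- filterRepeatedSameContext(recs)
  kept <- kept[kept$context == context, , drop = FALSE]
  ids <- unique(kept$individual_id)
  if (length(ids) < 4)
    stop("need at least 4 individuals with same-context repeated recordings")
  songs <- songs[songs$recording_id %in% kept$recording_id, , drop = FALSE]
  songs$recording_order <- kept$recording_order[
    match(songs$recording_id, kept$recording_id)]

  fixed <- c("date", "age", "order", if (includePosition) "position")
  spec1 <- modelSpec(trait, fixedTerms = fixed,
                     randomEffects = c("intercept", gradient),
                     priorFamily = priorFamily)
  slopes <- list()
  for (r in 1:2) {
    sr <- songs[songs$recording_order == r, , drop = FALSE]
    spec_r <- spec1
    spec_r@yearRandom <- length(unique(sr$year)) >= 2
    des <- buildDesign(sr, spec_r, firstRecordingOnly = FALSE)
    cfg <- chains1
    cfg@seed <- chains1@seed + r
    fit <- gibbsSample(des, cfg)
    slopes[[r]] <- extractSlopeDraws(fit, trait, gradient, context)
  }
  common <- intersect(colnames(slopes[[1]]), colnames(slopes[[2]]))
  missing_ids <- setdiff(ids, common)
  if (length(missing_ids))
    warning("individual(s) absent from a stage-1 fit, excluded: ",
            paste(missing_ids, collapse = ", "))
  if (length(common) < 4) stop("fewer than 4 individuals usable in stage 2")
  s1 <- slopes[[1]][, common, drop = FALSE]
  s2 <- slopes[[2]][, common, drop = FALSE]
  nd <- nrow(s1); m <- length(common)

  if (method == "per_draw") {
    if (is.null(chains2)) chains2 <- chainConfig(500, 200, 15, nChains = 1)
    d2 <- .stage2_design(common, 1L, priorFamily)
    rdraws <- unlist(lapply(seq_len(nd), function(s) {
      cfg <- chains2
      cfg@seed <- chains2@seed + s
      .stage2_fit(c(s1[s, ], s2[s, ]), d2, cfg)
    }))
  } else if (method == "stacked") {
    if (is.null(chains2)) chains2 <- chainConfig(6000, 1000, 5, nChains = 1)
    d2 <- .stage2_design(common, nd, priorFamily)
    rdraws <- .stage2_fit(c(as.vector(s1), as.vector(s2)), d2, chains2)
  } else {
    rdraws <- vapply(seq_len(nd), function(s) .icc_moments(s1[s, ], s2[s, ]),
                     numeric(1))
  }
  ci <- credibleInterval(rdraws)
  new("RepeatabilityResult", trait = trait, gradient = gradient,
      context = context, draws = rdraws, Rmean = mean(rdraws),
      ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
      nIndividuals = length(common), nSongs = nrow(songs))
}
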