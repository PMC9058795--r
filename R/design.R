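## Compile a song table + model specification into the response matrix, fixed
## design and random-effect block structures consumed by the Gibbs sampler.

.full_effect_names <- function(traits, effects)
  as.vector(t(outer(traits, effects, paste, sep = ":")))

#' Low-level design container
#'
#' Assembles a [DesignMatrices-class] directly from matrices, for models that
#' do not come from a song table (e.g. the stage-2 repeatability model or
#' closed-form oracle checks).  Each entry of \code{blocks} must contain
#' \code{name}, \code{levels}, \code{effectNames}, \code{cols} (levels x
#' effects matrix of design-column indices) and \code{rows} (list of
#' observation-row indices per level).
#'
#' @param Y response matrix (n x T).
#' @param W design matrix (fixed-effect columns first).
#' @param pFixed number of fixed-effect columns.
#' @param blocks list of random-effect block descriptors (may be empty).
#' @param spec a [ModelSpec-class] providing prior settings.
#' @param index optional per-row bookkeeping data.frame.
#' @param rowsDropped named integer vector of deletions.
#' @return a [DesignMatrices-class].
#' @export
designMatrices <- function(Y, W, pFixed, blocks = list(),
                           spec = modelSpec(colnames(Y)[1]),
                           index = data.frame(), rowsDropped = integer()) {
  Y <- as.matrix(Y); W <- as.matrix(W)
  if (is.null(colnames(Y))) colnames(Y) <- spec@responses
  fx <- colnames(W)[seq_len(pFixed)]
  if (is.null(fx)) fx <- sprintf("x%d", seq_len(pFixed))
  new("DesignMatrices", Y = Y, W = W, pFixed = as.integer(pFixed),
      fixedNames = fx, blocks = blocks, rowsDropped = rowsDropped,
      index = index, spec = spec)
}

#' Build design structures from a song table
#'
#' Applies the published data-preparation rules: keep each individual's first
#' recording (unless \code{firstRecordingOnly = FALSE}), listwise-delete songs
#' with a missing singing position or response, z-transform every continuous
#' variable over the retained rows, dummy-code context against the
#' male-stimulus reference, and form order-by-context interaction columns as
#' elementwise products of z(order) and the context dummies.  Context dummies
#' are omitted when a single context is present.  The individual random
#' structure (intercept, order-slope, position-slope) is laid out separately
#' per context; contexts with fewer than two individuals lose their random
#' block with a warning, as does the year block when fewer than two years
#' remain.
#'
#' @param songs song table as produced by [simulateSongs()] or read with
#'   [readSongTable()].
#' @param spec a [ModelSpec-class].
#' @param firstRecordingOnly keep only the first recording per individual.
#' @return a [DesignMatrices-class].
#' @export
buildDesign <- function(songs, spec, firstRecordingOnly = TRUE) {
  validObject(spec)
  songs <- as.data.frame(songs)
  bad_ctx <- setdiff(unique(songs$context), .CONTEXTS)
  if (length(bad_ctx))
    stop("unknown context label(s): ", paste(bad_ctx, collapse = ", "))
  dropped <- c(later_recordings = 0L, missing_position = 0L,
               missing_response = 0L)

  if (firstRecordingOnly && "recording_order" %in% names(songs)) {
    keep <- songs$recording_order ==
      ave(songs$recording_order, songs$individual_id, FUN = min)
    dropped["later_recordings"] <- sum(!keep)
    songs <- songs[keep, , drop = FALSE]
  }

  need_pos <- "position" %in% spec@fixedTerms ||
    "position" %in% spec@randomEffects
  if (need_pos) {
    miss <- is.na(songs$position)
    dropped["missing_position"] <- sum(miss)
    songs <- songs[!miss, , drop = FALSE]
  }
  missy <- !complete.cases(songs[, spec@responses, drop = FALSE])
  dropped["missing_response"] <- sum(missy)
  songs <- songs[!missy, , drop = FALSE]
  if (nrow(songs) < 3) stop("too few complete songs to build a design")

  zord <- zTransform(songs$song_order)
  Y <- vapply(spec@responses, function(r) zTransform(songs[[r]]),
              numeric(nrow(songs)))
  colnames(Y) <- spec@responses

  ctx_present <- intersect(.CONTEXTS, unique(songs$context))
  Xl <- list(`(Intercept)` = rep(1, nrow(songs)))
  if ("date" %in% spec@fixedTerms) Xl$date <- zTransform(songs$date)
  if ("age" %in% spec@fixedTerms) Xl$age <- as.numeric(songs$age)
  if ("order" %in% spec@fixedTerms) Xl$order <- zord
  if (need_pos && "position" %in% spec@fixedTerms)
    Xl$position <- zTransform(songs$position)
  if ("context" %in% spec@fixedTerms && length(ctx_present) > 1) {
    for (ctx in setdiff(ctx_present, ctx_present[1])) {
      Xl[[paste0("context_", ctx)]] <- as.numeric(songs$context == ctx)
      if ("order_context" %in% spec@fixedTerms)
        Xl[[paste0("order:context_", ctx)]] <-
          zord * as.numeric(songs$context == ctx)
    }
  }
  X <- do.call(cbind, Xl)
  colnames(X) <- names(Xl)

  grads <- list(intercept = rep(1, nrow(songs)), order = zord)
  if (need_pos) grads$position <- zTransform(songs$position)
  effects <- intersect(c("intercept", "order", "position"), spec@randomEffects)
  if (!need_pos) effects <- setdiff(effects, "position")

  Wl <- list(X)
  blocks <- list()
  p <- ncol(X)
  if (length(effects)) {
    for (ctx in ctx_present) {
      in_ctx <- songs$context == ctx
      ids <- unique(songs$individual_id[in_ctx])
      if (length(ids) < 2) {
        warning(sprintf(
          "context '%s' has %d individual(s); its random block was dropped",
          ctx, length(ids)))
        next
      }
      m <- length(ids); q <- length(effects)
      cols <- matrix(0L, m, q, dimnames = list(ids, effects))
      Z <- matrix(0, nrow(songs), m * q)
      rows <- vector("list", m)
      for (j in seq_len(m)) {
        rj <- which(songs$individual_id == ids[j] & in_ctx)
        rows[[j]] <- rj
        for (e in seq_len(q)) {
          cc <- (j - 1L) * q + e
          Z[rj, cc] <- grads[[effects[e]]][rj]
          cols[j, e] <- p + cc
        }
      }
      Wl[[length(Wl) + 1L]] <- Z
      blocks[[length(blocks) + 1L]] <- list(
        name = paste0("individual:", ctx), type = "individual", context = ctx,
        levels = ids, effectNames = effects, cols = cols, rows = rows)
      p <- p + m * q
    }
  }
  if (spec@yearRandom) {
    yrs <- sort(unique(songs$year))
    if (length(yrs) < 2) {
      warning("fewer than 2 year levels; year random block dropped")
    } else {
      m <- length(yrs)
      Z <- matrix(0, nrow(songs), m)
      cols <- matrix(0L, m, 1, dimnames = list(as.character(yrs), "intercept"))
      rows <- vector("list", m)
      for (j in seq_len(m)) {
        rj <- which(songs$year == yrs[j])
        rows[[j]] <- rj
        Z[rj, j] <- 1
        cols[j, 1] <- p + j
      }
      Wl[[length(Wl) + 1L]] <- Z
      blocks[[length(blocks) + 1L]] <- list(
        name = "year", type = "year", context = NA_character_,
        levels = as.character(yrs), effectNames = "intercept",
        cols = cols, rows = rows)
      p <- p + m
    }
  }
  W <- do.call(cbind, Wl)
  colnames(W) <- c(colnames(X), rep("", ncol(W) - ncol(X)))
  idx_cols <- intersect(c("individual_id", "recording_id", "year", "context",
                          "song_order"), names(songs))
  designMatrices(Y, W, ncol(X), blocks, spec = spec,
                 index = songs[, idx_cols, drop = FALSE],
                 rowsDropped = dropped)
}
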