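## Synthetic-data generator: inverts the reaction-norm model so that every
## downstream stage can be tested against known ground truth.

## matrix square root that tolerates singular / zero covariance matrices
.mvn_draw <- function(n, Sigma) {
  d <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("covariance matrix is not positive semi-definite")
  S <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(n * d), n, d) %*% S
}

.effect_names <- function(traits)
  as.vector(t(outer(traits, c("intercept", "order_slope", "position_slope"),
                    paste, sep = "_")))

#' Simulate focal individuals, their recordings and reaction-norm truth
#'
#' Each individual is assigned one social context, an age class and one (or,
#' for a configured fraction, two) recordings with year and date.  Individual
#' reaction-norm deviations (intercept, order-slope, position-slope per trait)
#' are drawn from the context-specific covariance matrix \code{G[context]};
#' recording-level slope drift with sd \code{repeatNoiseSd} makes the true
#' slope repeatability \code{Var_among / (Var_among + repeatNoiseSd^2)}.
#'
#' @param config a [SimulationConfig-class].
#' @param params a [TrueParameters-class].
#' @param seed RNG seed (defaults to the config's seed).
#' @return list with data.frames \code{individuals} (individual_id, context,
#'   age), \code{recordings} (individual_id, recording_id, recording_order,
#'   context, year, date) and \code{truth} (one row per recording with the
#'   realised intercepts and slopes per trait).
#' @export
simulateIndividuals <- function(config, params, seed = NULL) {
  validObject(config); validObject(params)
  for (ctx in .CONTEXTS) {
    bad <- .check_cov(params@G[[ctx]], sprintf("G[%s]", ctx))
    if (!is.null(bad)) stop(bad)
  }
  set.seed(if (is.null(seed)) config@seed else seed)
  n <- config@nIndividuals
  traits <- params@traits
  Tt <- length(traits)

  ids <- sprintf("ind%03d", seq_len(n))
  context <- sample(.CONTEXTS, n, replace = TRUE, prob = config@contextProbs)
  age <- rbinom(n, 1, 0.5)
  individuals <- data.frame(individual_id = ids, context = context, age = age,
                            stringsAsFactors = FALSE)

  n_rep <- round(config@propRepeated * n)
  repeated <- if (n_rep > 0) sample(ids, n_rep) else character()

  rec <- list(); tru <- list()
  slope_idx <- as.vector(vapply(seq_len(Tt) - 1L, function(t) 3L * t + c(2L, 3L),
                                integer(2)))
  for (i in seq_len(n)) {
    ctx1 <- context[i]
    base <- as.vector(.mvn_draw(1, params@G[[ctx1]]))
    n_recs <- if (ids[i] %in% repeated) 2L else 1L
    same_ctx <- runif(1) < config@propRepeatedSameContext
    year1 <- sample.int(config@nYears, 1)
    date1 <- runif(1, 0, 26)
    for (r in seq_len(n_recs)) {
      if (r == 1L) {
        ctx <- ctx1; dev <- base; year <- year1; date <- date1
      } else if (same_ctx) {
        ctx <- ctx1; dev <- base
        year <- year1; date <- min(26, date1 + runif(1, 1, 10))
      } else {
        ctx <- sample(setdiff(.CONTEXTS, ctx1), 1)
        dev <- as.vector(.mvn_draw(1, params@G[[ctx]]))
        year <- year1; date <- min(26, date1 + runif(1, 1, 10))
      }
      if (params@repeatNoiseSd > 0)
        dev[slope_idx] <- dev[slope_idx] +
          rnorm(length(slope_idx), 0, params@repeatNoiseSd)
      rec[[length(rec) + 1L]] <- data.frame(
        individual_id = ids[i],
        recording_id = sprintf("%s_rec%d", ids[i], r),
        recording_order = r, context = ctx, year = year, date = date,
        stringsAsFactors = FALSE)
      tr <- as.data.frame(as.list(setNames(dev, .effect_names(traits))))
      tru[[length(tru) + 1L]] <- cbind(rec[[length(rec)]][
        c("individual_id", "recording_id", "recording_order", "context")], tr)
    }
  }
  list(individuals = individuals,
       recordings = do.call(rbind, rec),
       truth = do.call(rbind, tru))
}

#' Simulate song-level trait values
#'
#' For every recording, draws the number of songs, song orders, singing
#' positions and residuals, and assembles each trait value on the z-scale as
#' fixed effects + year effect + individual intercept + order-slope x z(order)
#' + position-slope x z(position) + residual, with residuals drawn jointly
#' across traits.  Continuous covariates are z-transformed over the full
#' simulated table before entering the linear predictor; the raw values are
#' emitted so that model fitting performs its own standardisation.  Positions
#' are generated for every song (the bird always sings from somewhere) and
#' masked to missing afterwards with the configured probability.
#'
#' @param sim output of [simulateIndividuals()].
#' @param params a [TrueParameters-class].
#' @param config a [SimulationConfig-class].
#' @param seed RNG seed (defaults to config's seed + 1).
#' @param rescale if TRUE, map the z-scale trait values to natural units
#'   (seconds / Hz / ratio) with fixed affine transforms.
#' @return list with \code{songs} (one row per song) and \code{linpred} (the
#'   noiseless linear predictor per trait, for generator checks).
#' @export
simulateSongs <- function(sim, params, config, seed = NULL, rescale = FALSE) {
  validObject(config); validObject(params)
  recs <- sim$recordings
  if (!all(recs$recording_id %in% sim$truth$recording_id))
    stop("truth table must cover all recordings")
  set.seed(if (is.null(seed)) config@seed + 1L else seed)
  traits <- params@traits
  Tt <- length(traits)
  ind <- sim$individuals
  age_of <- setNames(ind$age, ind$individual_id)
  year_eff <- .mvn_draw(config@nYears, params@Vyear)

  rng <- config@songsPerRecording[1]:config@songsPerRecording[2]
  n_songs <- rng[sample.int(length(rng), nrow(recs), replace = TRUE)]
  songs <- data.frame(
    individual_id = rep(recs$individual_id, n_songs),
    recording_id = rep(recs$recording_id, n_songs),
    recording_order = rep(recs$recording_order, n_songs),
    year = rep(recs$year, n_songs),
    date = rep(recs$date, n_songs),
    context = rep(recs$context, n_songs),
    stringsAsFactors = FALSE)
  songs$age <- as.integer(age_of[songs$individual_id])
  songs$song_order <- unlist(lapply(n_songs, seq_len), use.names = FALSE)
  songs$position <- 100 * rbeta(nrow(songs), config@positionShape[1],
                                config@positionShape[2])

  zord <- zTransform(songs$song_order)
  zpos <- zTransform(songs$position)
  zdate <- zTransform(songs$date)
  ctxF <- as.numeric(songs$context == "female")
  ctxN <- as.numeric(songs$context == "none")
  X <- cbind(intercept = 1, date = zdate, age = songs$age, order = zord,
             position = zpos, context_female = ctxF, context_none = ctxN,
             order_context_female = zord * ctxF,
             order_context_none = zord * ctxN)

  tru <- sim$truth[match(songs$recording_id, sim$truth$recording_id), ,
                   drop = FALSE]
  resid <- .mvn_draw(nrow(songs), params@Rresid)
  lp <- matrix(0, nrow(songs), Tt, dimnames = list(NULL, traits))
  for (t in seq_len(Tt)) {
    tr <- traits[t]
    lp[, t] <- as.vector(X %*% params@beta[tr, ]) +
      year_eff[songs$year, t] +
      tru[[paste0(tr, "_intercept")]] +
      tru[[paste0(tr, "_order_slope")]] * zord +
      tru[[paste0(tr, "_position_slope")]] * zpos
    songs[[tr]] <- lp[, t] + resid[, t]
  }
  if (rescale) {
    maps <- .natural_maps()
    for (tr in intersect(traits, names(maps)))
      songs[[tr]] <- maps[[tr]](songs[[tr]])
  }
  miss <- runif(nrow(songs)) < config@missingPositionProb
  songs$position[miss] <- NA_real_
  linpred <- cbind(songs[c("individual_id", "recording_id", "song_order")],
                   as.data.frame(lp))
  list(songs = songs, linpred = linpred)
}

## fixed affine maps from the z-scale to natural units
.natural_maps <- function() list(
  SL = function(v) pmin(pmax(4 + 0.6 * v, 2.5), 6.5),
  MF = function(v) 6500 + 600 * v,
  complexity = function(v) pmin(pmax(0.55 + 0.12 * v, 0.02), 1))

#' One-call synthetic dataset
#'
#' Runs [simulateIndividuals()] then [simulateSongs()].
#'
#' @param config a [SimulationConfig-class].
#' @param params a [TrueParameters-class].
#' @param seed RNG seed (defaults to the config's).
#' @param rescale passed to [simulateSongs()].
#' @return list with individuals, recordings, truth, songs and linpred.
#' @export
simulateSongData <- function(config = simulationConfig(),
                             params = defaultTrueParameters(),
                             seed = NULL, rescale = FALSE) {
  sim <- simulateIndividuals(config, params, seed = seed)
  out <- simulateSongs(sim, params, config,
                       seed = if (is.null(seed)) NULL else seed + 1L,
                       rescale = rescale)
  c(sim, out)
}

#' Simulate syllable tables with known type structure
#'
#' Generates \code{KTrue} well-separated Gaussian clusters in the 5-feature
#' space (duration, minimum frequency, maximum frequency, bandwidth, mean
#' frequency) and draws each song's syllables so that the number of distinct
#' true types divided by the syllable count matches the song's complexity
#' within rounding, and syllable onsets/durations tile the song length
#' exactly.  Cluster centres are spread along the minimum-frequency axis so
#' separation scales as \code{6000 / KTrue} Hz.
#'
#' @param songs song table with columns song_id (or recording_id+song_order),
#'   SL and complexity.  If trait values are on the z-scale (the generator
#'   default) they are mapped to natural units internally.
#' @param KTrue number of true syllable types.
#' @param clusterSpread within-cluster sd of the frequency features, Hz.
#' @param seed RNG seed.
#' @param naturalScale set TRUE if SL / complexity are already in seconds /
#'   ratio units.
#' @return data.frame of syllables: song_id, onset, duration, min_freq,
#'   max_freq, bandwidth, mean_freq, true_type.
#' @export
simulateSyllables <- function(songs, KTrue, clusterSpread = 50, seed = 1,
                              naturalScale = FALSE) {
  if (KTrue < 1) stop("KTrue must be >= 1")
  set.seed(seed)
  if (!"song_id" %in% names(songs))
    songs$song_id <- paste(songs$recording_id, songs$song_order, sep = "_s")
  maps <- .natural_maps()
  sl <- if (naturalScale) songs$SL else maps$SL(songs$SL)
  cx <- if (naturalScale) songs$complexity else maps$complexity(songs$complexity)
  if (any(cx <= 0 | cx > 1)) stop("complexity targets must lie in (0, 1]")

  cent <- data.frame(
    dur = runif(KTrue, 0.08, 0.3),
    minf = 2000 + 6000 * (seq_len(KTrue) - 0.5) / KTrue,
    bw = runif(KTrue, 500, 2500),
    relmean = runif(KTrue, 0.3, 0.7))

  out <- vector("list", nrow(songs))
  for (i in seq_len(nrow(songs))) {
    n_syl <- max(1L, round(sl[i] / 0.25))
    d <- max(1L, round(cx[i] * n_syl))
    if (d > n_syl) d <- n_syl
    if (d > KTrue)
      stop(sprintf("song %s needs %d distinct types but only %d exist",
                   songs$song_id[i], d, KTrue))
    types <- sample.int(KTrue, d)
    labels <- c(types, types[sample.int(d, n_syl - d, replace = TRUE)])
    labels <- labels[sample.int(n_syl)]
    dur <- pmax(0.02, cent$dur[labels] * (1 + rnorm(n_syl, 0, clusterSpread * 1e-4)))
    if (n_syl == 1L) {
      dur <- sl[i]; onset <- 0
    } else if (sum(dur) + 0.01 * (n_syl - 1) > sl[i]) {
      f <- sl[i] / (sum(dur) + 0.01 * (n_syl - 1))
      dur <- dur * f
      onset <- cumsum(c(0, head(dur, -1) + 0.01 * f))
    } else {
      gap <- (sl[i] - sum(dur)) / (n_syl - 1)
      onset <- cumsum(c(0, head(dur, -1) + gap))
    }
    minf <- cent$minf[labels] + rnorm(n_syl, 0, clusterSpread)
    bw <- pmax(50, cent$bw[labels] + rnorm(n_syl, 0, clusterSpread))
    relm <- pmin(0.95, pmax(0.05, cent$relmean[labels] +
                              rnorm(n_syl, 0, clusterSpread * 4e-4)))
    out[[i]] <- data.frame(
      song_id = songs$song_id[i], onset = onset, duration = dur,
      min_freq = minf, max_freq = minf + bw, bandwidth = bw,
      mean_freq = minf + relm * bw, true_type = labels,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated dataset to disk
#'
#' Writes songs.csv, truth_reaction_norms.csv, recordings.csv, linpred.csv and
#' truth_parameters.json (and syllables.csv when provided) into \code{dir}.
#'
#' @param sim output of [simulateSongData()].
#' @param dir output directory (created if needed).
#' @param params the [TrueParameters-class] used (optional, for the truth
#'   parameter file).
#' @param syllables optional syllable table.
#' @return invisibly, the vector of files written.
#' @export
saveSimulation <- function(sim, dir, params = NULL, syllables = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(songs = file.path(dir, "songs.csv"),
             truth = file.path(dir, "truth_reaction_norms.csv"),
             recordings = file.path(dir, "recordings.csv"),
             linpred = file.path(dir, "linpred.csv"))
  writeSongTable(sim$songs, files["songs"])
  write.csv(sim$truth, files["truth"], row.names = FALSE)
  write.csv(sim$recordings, files["recordings"], row.names = FALSE)
  write.csv(sim$linpred, files["linpred"], row.names = FALSE)
  if (!is.null(syllables)) {
    files["syllables"] <- file.path(dir, "syllables.csv")
    write.csv(syllables, files["syllables"], row.names = FALSE)
  }
  if (!is.null(params)) {
    files["parameters"] <- file.path(dir, "truth_parameters.json")
    jsonlite::write_json(
      list(traits = params@traits, beta = params@beta,
           G = params@G, Vyear = params@Vyear, Rresid = params@Rresid,
           repeatNoiseSd = params@repeatNoiseSd),
      files["parameters"], digits = NA, matrix = "columnmajor")
  }
  invisible(files)
}
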