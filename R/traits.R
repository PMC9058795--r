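## Song-trait derivation from syllable tables: k-means syllable typing,
## short-term complexity, maximum frequency, song length, z-standardisation.

.FEATURES <- c("duration", "min_freq", "max_freq", "bandwidth", "mean_freq")

## k-means++ seeding: spread initial centres by sampling points with
## probability proportional to squared distance from the chosen set
.kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (k in seq_len(K - 1L)) {
    if (all(d2 == 0)) {
      idx[k + 1L] <- sample.int(n, 1)
    } else {
      idx[k + 1L] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[k + 1L], ])^2))
  }
  idx
}

#' Classify syllables into types by k-means
#'
#' Clusters syllables in the 5-dimensional spectro-acoustic feature space
#' (duration, minimum frequency, maximum frequency, bandwidth, mean frequency)
#' with k-means (Hartigan-Wong), keeping the best of \code{nRestarts} random
#' starts by within-cluster sum of squares.  The published analysis used
#' K = 200 types; K must not exceed the number of syllables.
#'
#' @param features numeric matrix or data.frame of syllable features (N x 5,
#'   or any numeric columns).
#' @param K number of syllable types (default 200).
#' @param seed RNG seed making the restarts deterministic.
#' @param nRestarts number of random restarts.
#' @param standardize z-score the features before clustering (default FALSE;
#'   clustering runs on the raw feature scales).
#' @return list of class \code{SyllableTypeModel}: K, centroids (K x 5),
#'   assignment (length N), inertia (total within-cluster sum of squares).
#' @export
fitSyllableTypes <- function(features, K = 200, seed = 1, nRestarts = 10,
                             standardize = FALSE) {
  X <- as.matrix(as.data.frame(features)[
    , intersect(.FEATURES, colnames(as.data.frame(features))), drop = FALSE])
  if (ncol(X) == 0) X <- as.matrix(features)
  if (!all(is.finite(X))) stop("syllable features must be finite")
  if (nrow(X) < K)
    stop(sprintf("cannot form %d syllable types from %d syllables", K, nrow(X)))
  if (standardize) X <- scale(X)
  set.seed(seed)
  if (nrow(X) == K) {
    # each syllable its own type
    return(structure(list(K = K, centroids = X,
                          assignment = seq_len(K), inertia = 0),
                     class = "SyllableTypeModel"))
  }
  best <- NULL
  for (r in seq_len(nRestarts)) {
    km_r <- suppressWarnings(
      stats::kmeans(X, centers = X[.kmeanspp_init(X, K), , drop = FALSE],
                    iter.max = 100))
    if (is.null(best) || km_r$tot.withinss < best$tot.withinss) best <- km_r
  }
  km <- best
  structure(list(K = K, centroids = km$centers, assignment = km$cluster,
                 inertia = km$tot.withinss),
            class = "SyllableTypeModel")
}

#' Short-term song complexity
#'
#' Number of distinct syllable types divided by the total number of syllables
#' within the song; lies in (0, 1].
#'
#' @param labels syllable type labels of one song, in any order.
#' @return complexity ratio.
#' @export
songComplexity <- function(labels) {
  if (length(labels) == 0) stop("song has no syllables")
  length(unique(labels)) / length(labels)
}

#' Maximum frequency of a song
#'
#' The largest per-syllable mean frequency within the song.
#'
#' @param meanFreqs per-syllable mean frequencies (Hz) of one song.
#' @return maximum frequency, Hz.
#' @export
songMaxFrequency <- function(meanFreqs) {
  if (length(meanFreqs) == 0) stop("song has no syllables")
  max(meanFreqs)
}

#' Song length
#'
#' Duration from the onset of the first syllable to the offset of the last
#' syllable.
#'
#' @param onsets syllable onsets (s) of one song.
#' @param durations syllable durations (s).
#' @return song length in seconds.
#' @export
songLength <- function(onsets, durations) {
  if (length(onsets) == 0) stop("song has no syllables")
  if (!all(is.finite(onsets)) || !all(is.finite(durations)))
    stop("onsets and durations must be finite")
  if (any(durations <= 0)) stop("durations must be positive")
  sl <- max(onsets + durations) - min(onsets)
  if (sl <= 0) stop("non-positive song span")
  sl
}

#' z-transform preserving missing values and direction
#'
#' Centres and scales to mean 0, sd 1 (n - 1 denominator) over the
#' non-missing entries; missing entries stay missing and the original
#' direction is maintained.
#'
#' @param x numeric vector (may contain NA).
#' @return standardised vector of the same length.
#' @export
zTransform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values to z-transform")
  s <- sd(x[ok])
  if (s == 0) stop("cannot z-transform a constant vector")
  (x - mean(x[ok])) / s
}

#' Derive the three song traits from a syllable table
#'
#' Fits the syllable-type model on all syllables, then computes per song the
#' complexity (distinct types / syllable count), maximum frequency (largest
#' per-syllable mean frequency) and song length (first onset to last offset).
#'
#' @param syllables syllable table with columns song_id, onset, duration and
#'   the five spectro-acoustic features.
#' @param K number of syllable types (capped at the syllable count).
#' @param seed,nRestarts,standardize passed to [fitSyllableTypes()].
#' @return data.frame with song_id, SL (s), MF (Hz), complexity, plus the
#'   fitted model as attribute \code{"typeModel"}.
#' @export
deriveSongTraits <- function(syllables, K = 200, seed = 1, nRestarts = 10,
                             standardize = FALSE) {
  K <- min(K, nrow(syllables))
  model <- fitSyllableTypes(syllables, K = K, seed = seed,
                            nRestarts = nRestarts, standardize = standardize)
  syllables$.type <- model$assignment
  by_song <- split(syllables, syllables$song_id)
  out <- do.call(rbind, lapply(by_song, function(s) data.frame(
    song_id = s$song_id[1],
    SL = songLength(s$onset, s$duration),
    MF = songMaxFrequency(s$mean_freq),
    complexity = songComplexity(s$.type),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "typeModel") <- model
  out
}
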