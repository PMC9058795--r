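test_that("complexity is distinct types over syllable count", {
  expect_equal(songComplexity(c("A", "B", "A", "C")), 0.75)
  expect_equal(songComplexity(c("A", "A", "A", "A")), 0.25)
  expect_equal(songComplexity(letters[1:7]), 1.0)
  # permutation invariant
  expect_equal(songComplexity(c("C", "A", "B", "A")), 0.75)
  expect_error(songComplexity(character()), "no syllables")
})

test_that("maximum frequency is the largest per-syllable mean frequency", {
  expect_equal(songMaxFrequency(c(4100, 5300, 3200)), 5300)
  expect_equal(songMaxFrequency(4000), 4000)
  expect_equal(songMaxFrequency(rev(c(4100, 5300, 3200))), 5300)
  expect_error(songMaxFrequency(numeric()), "no syllables")
})

test_that("song length spans first onset to last offset", {
  expect_equal(songLength(0, 0.2), 0.2)
  expect_equal(songLength(c(0, 1, 3.2), c(0.2, 0.4, 0.3)), 3.5)
  expect_error(songLength(c(0, 1), c(0.5, -0.1)), "positive")
})

test_that("z-transform standardises, preserves NA and direction", {
  expect_equal(zTransform(c(1, 2, 3)), c(-1, 0, 1))
  z <- zTransform(c(5, NA, 9, 1))
  expect_true(is.na(z[2]))
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(sd(z, na.rm = TRUE), 1)
  # idempotence
  x <- rnorm(50)
  expect_equal(zTransform(zTransform(x)), zTransform(x), tolerance = 1e-12)
  # affine equivariance with direction maintained
  expect_equal(zTransform(-2 * x + 7), -zTransform(x), tolerance = 1e-12)
  expect_error(zTransform(c(5, 5, 5)), "constant")
  expect_error(zTransform(c(1, NA, NA)), "at least 2")
})

test_that("k-means typing matches the brute-force partition on two pairs", {
  # two tight pairs of points; enumerate all 3 bipartitions into two pairs,
  # pick the one with the smallest within-cluster sum of squares
  pts <- rbind(c(0, 0, 0, 0, 0), c(0.1, 0, 0, 0, 0),
               c(10, 10, 10, 10, 10), c(10, 10.1, 10, 10, 10))
  parts <- list(list(1:2, 3:4), list(c(1, 3), c(2, 4)), list(c(1, 4), c(2, 3)))
  wss <- vapply(parts, function(p) sum(vapply(p, function(ix) {
    ctr <- colMeans(pts[ix, , drop = FALSE])
    sum(sweep(pts[ix, , drop = FALSE], 2, ctr)^2)
  }, numeric(1))), numeric(1))
  best <- parts[[which.min(wss)]]
  model <- fitSyllableTypes(pts, K = 2, seed = 1, nRestarts = 5)
  got <- split(seq_len(4), model$assignment)
  expect_setequal(lapply(got, sort), lapply(best, sort))
  ctrs <- model$centroids[model$assignment[c(1, 3)], ]
  expect_equal(unname(ctrs[1, ]), colMeans(pts[1:2, ]))
  expect_equal(unname(ctrs[2, ]), colMeans(pts[3:4, ]))
})

test_that("k-means degenerate cases: K = N and K > N", {
  pts <- matrix(rnorm(25), 5, 5)
  model <- fitSyllableTypes(pts, K = 5, seed = 1, nRestarts = 2)
  expect_equal(model$inertia, 0, tolerance = 1e-10)
  expect_error(fitSyllableTypes(pts, K = 6), "cannot form")
})

test_that("syllable tables honour the feature and tiling invariants", {
  sim <- simulateSongData(smallConfig(nIndividuals = 10, songs = c(8, 15)),
                          uniParams())
  set.seed(42)
  sim$songs$complexity <- rnorm(nrow(sim$songs))
  syl <- simulateSyllables(sim$songs, KTrue = 25, clusterSpread = 30, seed = 2)
  expect_true(all(syl$min_freq <= syl$mean_freq + 1e-9))
  expect_true(all(syl$mean_freq <= syl$max_freq + 1e-9))
  expect_equal(syl$bandwidth, syl$max_freq - syl$min_freq)
  expect_true(all(syl$duration > 0))
  # onsets/durations tile the song's SL exactly
  sl_nat <- songplast:::.natural_maps()$SL(sim$songs$SL)
  ids <- paste(sim$songs$recording_id, sim$songs$song_order, sep = "_s")
  by_song <- split(syl, syl$song_id)
  got <- vapply(by_song, function(s) songLength(s$onset, s$duration),
                numeric(1))
  expect_equal(unname(got[ids]), sl_nat, tolerance = 1e-8)
  # complexity of true labels matches the target within rounding
  cx_nat <- songplast:::.natural_maps()$complexity(sim$songs$complexity)
  got_cx <- vapply(by_song, function(s) songComplexity(s$true_type),
                   numeric(1))[ids]
  n_syl <- vapply(by_song, nrow, integer(1))[ids]
  expect_true(all(abs(got_cx - cx_nat) <= 1 / n_syl + 1e-9))
})

test_that("complexity from a 4-syllable song with target 0.75 uses 3 types", {
  songs <- data.frame(song_id = "s1", recording_id = "r", song_order = 1,
                      SL = 1.0, complexity = 0.75)
  syl <- simulateSyllables(songs, KTrue = 10, clusterSpread = 1, seed = 1,
                           naturalScale = TRUE)
  expect_equal(nrow(syl), 4)
  expect_equal(length(unique(syl$true_type)), 3)
  expect_error(simulateSyllables(songs, KTrue = 2, clusterSpread = 1,
                                 naturalScale = TRUE), "distinct types")
})

test_that("derived traits agree with truth on separated clusters", {
  sim <- simulateSongData(smallConfig(nIndividuals = 12, songs = c(10, 18),
                                      seed = 3), uniParams(), seed = 3)
  set.seed(43)
  sim$songs$complexity <- rnorm(nrow(sim$songs))
  syl <- simulateSyllables(sim$songs, KTrue = 25, clusterSpread = 5, seed = 3)
  traits <- deriveSongTraits(syl, K = 25, seed = 3)
  by_song <- split(syl, syl$song_id)
  truth_cx <- vapply(by_song, function(s) songComplexity(s$true_type),
                     numeric(1))
  agree <- mean(abs(traits$complexity[match(names(truth_cx),
                                            traits$song_id)] - truth_cx) < 1e-9)
  expect_gte(agree, 0.99)
  # MF equals the max of syllable mean frequencies by construction
  truth_mf <- vapply(by_song, function(s) max(s$mean_freq), numeric(1))
  expect_equal(traits$MF[match(names(truth_mf), traits$song_id)],
               unname(truth_mf))
})
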