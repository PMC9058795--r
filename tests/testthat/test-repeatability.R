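test_that("same-context filter matches a brute-force enumeration", {
  set.seed(10)
  n <- 60
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    data.frame(individual_id = sprintf("b%02d", i),
               recording_id = sprintf("b%02d_r%d", i, seq_len(k)),
               date = sort(runif(k, 0, 30)),
               context = sample(c("male", "female", "none"), k, replace = TRUE))
  }))
  got <- filterRepeatedSameContext(recs)
  # brute force: individuals whose two earliest recordings share a context
  expected <- Filter(function(id) {
    rr <- recs[recs$individual_id == id, ]
    nrow(rr) >= 2 && {
      rr <- rr[order(rr$date), ]
      rr$context[1] == rr$context[2]
    }
  }, unique(recs$individual_id))
  expect_setequal(unique(got$individual_id), expected)
  expect_true(all(table(got$individual_id) == 2))
  expect_true(all(got$recording_order %in% 1:2))
  # a bird recorded in male then female context is excluded
  two <- data.frame(individual_id = "x", recording_id = c("x1", "x2"),
                    date = c(1, 2), context = c("male", "female"))
  expect_equal(nrow(filterRepeatedSameContext(two)), 0)
  # a bird with two male-context recordings is retained in date order
  two$context <- "male"
  two$date <- c(5, 2)
  kept <- filterRepeatedSameContext(two)
  expect_equal(kept$recording_id[kept$recording_order == 1], "x2")
})

test_that("slope draw extraction has the shape contract", {
  sim <- repeatScenario(Rtrue = 1, nIndividuals = 8, songs = 12, seed = 2)
  songs <- sim$songs[sim$songs$recording_order == 1, ]
  des <- buildDesign(songs, modelSpec("SL", randomEffects =
                                        c("intercept", "order")))
  fit <- gibbsSample(des, chainConfig(800, 200, 3, nChains = 1))
  sl <- extractSlopeDraws(fit, "SL", "order", "male")
  expect_equal(dim(sl), c(200L, 8L))
  expect_setequal(colnames(sl), unique(songs$individual_id))
  expect_error(extractSlopeDraws(fit, "SL", "position", "male"),
               "no random position")
})

test_that("zero slope variance shrinks extracted slope draws toward zero", {
  sim <- simulateSongData(smallConfig(nIndividuals = 20, songs = c(25, 25),
                                      seed = 3),
                          uniParams(ordVar = 0, posVar = 0), seed = 3)
  des <- buildDesign(sim$songs, modelSpec("SL", randomEffects =
                                            c("intercept", "order")))
  fit <- gibbsSample(des, chainConfig(2000, 500, 3, nChains = 1))
  sl <- extractSlopeDraws(fit, "SL", "order", "male")
  expect_lt(var(colMeans(sl)), 0.02)
})

test_that("stage-2 estimators agree on trivial variance structure", {
  # identical slopes across recordings: moment ICC = 1; pure noise: ~0
  s <- matrix(rnorm(40), 1)
  expect_equal(songplast:::.icc_moments(s, s), 1)
  set.seed(5)
  many <- replicate(200, songplast:::.icc_moments(rnorm(30), rnorm(30)))
  expect_lt(mean(many), 0.15)
  # equal among and within variance: ICC near 0.5
  set.seed(6)
  vals <- replicate(300, {
    a <- rnorm(60, 0, 1)
    songplast:::.icc_moments(a + rnorm(60), a + rnorm(60))
  })
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
})

test_that("two-step pipeline recovers strong repeatability and needs >= 4 birds", {
  sim <- repeatScenario(Rtrue = 1, nIndividuals = 20, songs = 25, seed = 4)
  songs <- sim$songs
  res <- slopeRepeatability(songs, "SL", "order", "male",
                            chains1 = chainConfig(3000, 500, 5, nChains = 1),
                            method = "moment")
  expect_s4_class(res, "RepeatabilityResult")
  expect_gt(res@Rmean, 0.55)
  expect_true(all(res@draws >= 0 & res@draws <= 1))
  few <- songs[songs$individual_id %in% unique(songs$individual_id)[1:2], ]
  expect_error(slopeRepeatability(few, "SL", "order", "male"),
               "at least 4")
})

test_that("stacked and per-draw stage-2 methods disagree as documented", {
  # with recording-level slope drift the stacked estimator absorbs half the
  # drift into the among-individual component and sits above the per-draw
  # estimate
  sim <- repeatScenario(Rtrue = 0.3, nIndividuals = 25, songs = 20, seed = 7)
  r_stacked <- slopeRepeatability(sim$songs, "SL", "order", "male",
                                  chains1 = chainConfig(3000, 500, 5,
                                                        nChains = 1),
                                  method = "stacked")
  r_moment <- slopeRepeatability(sim$songs, "SL", "order", "male",
                                 chains1 = chainConfig(3000, 500, 5,
                                                       nChains = 1),
                                 method = "moment")
  expect_gt(r_stacked@Rmean, r_moment@Rmean)
})
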