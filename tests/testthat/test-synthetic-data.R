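test_that("individual deviations recover the context covariance moments", {
  # 6x6 bivariate male-context block, n large enough for a 3-SE band
  par <- defaultTrueParameters()
  cfg <- simulationConfig(nIndividuals = 10000, propRepeated = 0, seed = 3)
  sim <- simulateIndividuals(cfg, par, seed = 3)
  eff <- songplast:::.effect_names(par@traits)
  for (ctx in c("male", "female", "none")) {
    tr <- sim$truth[sim$truth$context == ctx, eff]
    n <- nrow(tr)
    emp <- cov(as.matrix(tr))
    G <- par@G[[ctx]]
    for (i in 1:6) for (j in i:6) {
      # SE of a sample covariance of a bivariate normal
      se <- sqrt((G[i, i] * G[j, j] + G[i, j]^2) / (n - 1))
      expect_lt(abs(emp[i, j] - G[i, j]), 3.5 * se)
    }
  }
})

test_that("degenerate and deterministic generator cases behave exactly", {
  par <- uniParams(intVar = 0, ordVar = 0, posVar = 0)
  cfg <- smallConfig(nIndividuals = 10)
  sim <- simulateIndividuals(cfg, par)
  eff <- songplast:::.effect_names("SL")
  expect_true(all(as.matrix(sim$truth[, eff]) == 0))

  # all-male assignment under degenerate context probabilities
  cfg2 <- smallConfig(nIndividuals = 50,
                      contextProbs = c(male = 1, female = 0, none = 0))
  sim2 <- simulateIndividuals(cfg2, uniParams())
  expect_true(all(sim2$individuals$context == "male"))

  # zero variance everywhere + intercept 1 -> every trait value exactly 1
  par3 <- uniParams(intVar = 0, ordVar = 0, posVar = 0, residVar = 0,
                    yearVar = 0, beta = c(intercept = 1))
  cfg3 <- smallConfig(nIndividuals = 5, songs = c(5, 5), missing = 0)
  sim3 <- simulateSongData(cfg3, par3)
  expect_equal(sim3$songs$SL, rep(1, nrow(sim3$songs)))
})

test_that("non-PSD covariance is rejected with the offending context named", {
  par <- uniParams()
  G <- diag(3); G[1, 2] <- G[2, 1] <- 2          # not PSD
  par@G$female <- G
  expect_error(simulateIndividuals(smallConfig(
    contextProbs = c(male = .4, female = .4, none = .2)), par),
    "G\\[female\\]")
})

test_that("trait values equal the recorded linear predictor plus residual", {
  par <- uniParams(residVar = 0)
  cfg <- smallConfig(nIndividuals = 20, missing = 0.2)
  sim <- simulateSongData(cfg, par)
  # zero residual variance: values reproduce the linear predictor exactly
  expect_equal(sim$songs$SL, sim$linpred$SL, tolerance = 1e-12)

  # with residual noise the regression of trait on linear predictor has
  # slope 1 and intercept 0 up to Monte-Carlo error
  par2 <- uniParams()
  sim2 <- simulateSongData(smallConfig(nIndividuals = 80, seed = 4), par2,
                           seed = 4)
  fit <- lm(sim2$songs$SL ~ sim2$linpred$SL)
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  expect_lt(abs(coef(fit)[1]), 0.05)
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- smallConfig(nIndividuals = 12, propRepeated = 0.4, seed = 9)
  par <- defaultTrueParameters()
  a <- simulateSongData(cfg, par)
  b <- simulateSongData(cfg, par)
  expect_identical(a$songs, b$songs)
  expect_identical(a$truth, b$truth)
})

test_that("missing-position fraction stays within binomial 99% bounds", {
  cfg <- smallConfig(nIndividuals = 60, songs = c(20, 40), missing = 0.15,
                     seed = 2)
  sim <- simulateSongData(cfg, uniParams(), seed = 2)
  n <- nrow(sim$songs)
  phat <- mean(is.na(sim$songs$position))
  half <- qnorm(0.995) * sqrt(0.15 * 0.85 / n)
  expect_lt(abs(phat - 0.15), half + 1e-12)
})

test_that("a configured order-by-context interaction is recovered by OLS", {
  # female-context interaction beta = 0.285 (a published fixed-effect
  # magnitude used as a generator setting); among female-context songs the
  # OLS slope of trait on z(order) approximates beta_order + 0.285
  par <- uniParams(intVar = 0.05, ordVar = 0, posVar = 0,
                   beta = c(order = 0.044, order_context_female = 0.285))
  cfg <- smallConfig(nIndividuals = 400, songs = c(20, 20),
                     contextProbs = c(male = .5, female = .5, none = 0),
                     missing = 0, seed = 6)
  sim <- simulateSongData(cfg, par, seed = 6)
  s <- sim$songs
  zord <- zTransform(s$song_order)
  fem <- s$context == "female"
  sl <- coef(lm(s$SL[fem] ~ zord[fem]))[2]
  expect_lt(abs(sl - (0.044 + 0.285)), 0.04)
})

test_that("songs-per-recording honours a degenerate range", {
  cfg <- smallConfig(nIndividuals = 8, songs = c(30, 30))
  sim <- simulateSongData(cfg, uniParams())
  expect_true(all(table(sim$songs$recording_id) == 30))
  expect_true(all(unlist(tapply(sim$songs$song_order, sim$songs$recording_id,
                                function(x) identical(sort(x), 1:30)))))
})
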