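test_that("retained-draw bookkeeping follows floor((n - burnin) / thin)", {
  expect_equal(retainedSamples(publishedChains()), 1000L)
  expect_equal(retainedSamples(chainConfig(1000, 0, 1, nChains = 1)), 1000L)
  expect_equal(retainedSamples(chainConfig(10000, 1000, 7, nChains = 1)),
               1285L)
  # burn-in consuming every iteration is rejected outright
  expect_error(chainConfig(1000, 1000, 1), "burnIn")
})

test_that("with fixed covariances the sampler matches the GLS posterior", {
  set.seed(42)
  n <- 100
  X <- cbind(1, rnorm(n), runif(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  R <- matrix(c(1, 0.5, 0.5, 2), 2)
  Y <- X %*% cbind(c(0.5, -1, 2), c(1, 0.3, -0.5)) +
    matrix(rnorm(n * 2), n) %*% chol(R)
  colnames(Y) <- c("a", "b")
  des <- designMatrices(Y, X, 3, spec = modelSpec(c("a", "b")))
  fit <- gibbsSample(des, chainConfig(2200, 200, 1, nChains = 1),
                     updateResid = FALSE, Rinit = R)
  bd <- betaDraws(fit)
  Rinv <- solve(R)
  gls <- solve(kronecker(Rinv, crossprod(X)),
               as.vector(crossprod(X, Y %*% Rinv)))
  mcse <- apply(bd, 2, sd) / sqrt(nrow(bd))   # draws are iid here
  expect_true(all(abs(colMeans(bd) - gls) < 3 * mcse))
})

test_that("with no data the sampler reproduces its priors", {
  blk <- list(name = "g", type = "individual", context = NA,
              levels = character(), effectNames = c("intercept", "order"),
              cols = matrix(integer(), 0, 2), rows = list())
  spec <- modelSpec("y", priorFamily = "inverse_wishart", priorNu = 7,
                    priorScale = 2)
  des <- designMatrices(matrix(numeric(), 0, 1, dimnames = list(NULL, "y")),
                        matrix(numeric(), 0, 1), 1L, blocks = list(blk),
                        spec = spec)
  fit <- gibbsSample(des, chainConfig(8000, 0, 1, nChains = 1), saveU = FALSE)
  G <- varianceDraws(fit, "g")
  # IW(nu, S) mean = S / (nu - d - 1) = 2I / 4
  expect_equal(unname(diag(apply(G, c(2, 3), mean))), c(0.5, 0.5),
               tolerance = 0.1)
  expect_equal(sd(betaDraws(fit)[, 1]), 1e4, tolerance = 0.1)
})

test_that("retained covariance draws are symmetric positive definite", {
  sim <- simulateSongData(smallConfig(nIndividuals = 15, seed = 5),
                          uniParams(), seed = 5)
  fit <- gibbsSample(buildDesign(sim$songs, modelSpec("SL")),
                     chainConfig(600, 100, 2, nChains = 1))
  for (comp in c("individual:male", "year", "resid")) {
    arr <- varianceDraws(fit, comp)
    for (s in seq_len(dim(arr)[1])) {
      M <- arr[s, , , drop = TRUE]
      if (is.null(dim(M))) M <- matrix(M, 1, 1)
      expect_lt(max(abs(M - t(M))), 1e-10)
      expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
  # implied correlations lie in [-1, 1]
  G <- varianceDraws(fit, "individual:male")
  r <- G[, 1, 2] / sqrt(G[, 1, 1] * G[, 2, 2])
  expect_true(all(abs(r) <= 1))
})

test_that("both prior families give overlapping slope-variance intervals", {
  sim <- simulateSongData(smallConfig(nIndividuals = 40, songs = c(15, 15),
                                      seed = 6), uniParams(), seed = 6)
  des <- buildDesign(sim$songs, modelSpec("SL"))
  cis <- lapply(c("parameter_expanded", "inverse_wishart"), function(fam) {
    fit <- gibbsSample(des, chainConfig(3000, 500, 5, nChains = 1),
                       priorFamily = fam, saveU = FALSE)
    credibleInterval(varianceDraws(fit, "individual:male")[, "SL:order",
                                                           "SL:order"])
  })
  expect_lt(max(cis[[1]]["low"], cis[[2]]["low"]),
            min(cis[[1]]["high"], cis[[2]]["high"]))
})

test_that("split-Rhat flags disagreement and passes consistent chains", {
  set.seed(1)
  m <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(gelmanRubin(m), 1.01)
  # disjoint supports (rank normalisation bounds the statistic, but it sits
  # far above the conventional 1.1 threshold)
  expect_gt(gelmanRubin(cbind(rnorm(500), rnorm(500) + 50)), 1.5)
  # an exactly duplicated chain
  x <- rnorm(1000)
  expect_lt(abs(gelmanRubin(cbind(x, x)) - 1), 0.01)
  expect_error(gelmanRubin(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("per-parameter Rhat on a real fit is near 1 for fixed effects", {
  sim <- simulateSongData(smallConfig(nIndividuals = 20, seed = 7),
                          uniParams(), seed = 7)
  fit <- gibbsSample(buildDesign(sim$songs, modelSpec("SL")),
                     chainConfig(1500, 500, 2, nChains = 2), saveU = FALSE)
  gr <- gelmanRubin(fit)
  expect_true(all(gr[grep("^SL:", names(gr))] < 1.1))
  expect_error(gelmanRubin(
    gibbsSample(buildDesign(sim$songs, modelSpec("SL")),
                chainConfig(300, 100, 2, nChains = 1), saveU = FALSE)),
    "2 chains")
})
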