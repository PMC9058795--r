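# Shared synthetic scenarios for the test suite.  Everything is generated in
# code; sizes are kept small so the default run stays fast.

# univariate ground truth with a single free trait name and simple diagonal
# covariance structure
uniParams <- function(trait = "SL", intVar = 0.2, ordVar = 0.15,
                      posVar = 0.05, residVar = 0.6, yearVar = 0.05,
                      beta = NULL, repeatNoiseSd = 0) {
  b <- matrix(0, 1, 9,
              dimnames = list(trait, songplast:::.BETA_TERMS))
  if (!is.null(beta)) b[1, names(beta)] <- beta
  G <- diag(c(intVar, ordVar, posVar))
  trueParameters(trait, b,
                 G = list(male = G, female = G, none = G),
                 Vyear = matrix(yearVar), Rresid = matrix(residVar),
                 repeatNoiseSd = repeatNoiseSd)
}

smallConfig <- function(nIndividuals = 30, songs = c(10, 20), nYears = 3,
                        contextProbs = c(male = 1, female = 0, none = 0),
                        propRepeated = 0, missing = 0.1, seed = 1, ...) {
  simulationConfig(nIndividuals = nIndividuals, songsPerRecording = songs,
                   nYears = nYears, contextProbs = contextProbs,
                   propRepeated = propRepeated,
                   missingPositionProb = missing, seed = seed, ...)
}

# repeated-recordings scenario with a chosen true slope repeatability
repeatScenario <- function(Rtrue, nIndividuals = 40, songs = 30, seed = 5,
                           ordVar = 0.15) {
  noise <- if (Rtrue >= 1) 0 else sqrt(ordVar * (1 - Rtrue) / Rtrue)
  par <- uniParams(ordVar = ordVar, repeatNoiseSd = noise)
  cfg <- smallConfig(nIndividuals = nIndividuals, songs = c(songs, songs),
                     propRepeated = 1, seed = seed)
  cfg@propRepeatedSameContext <- 1
  simulateSongData(cfg, par, seed = seed)
}
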