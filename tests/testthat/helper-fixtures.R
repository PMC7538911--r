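# Shared fixtures, built in code at test time.

# A ground truth + fitted/scaled direction pair from the model-building
# simulation, cached per session (several test files reuse it).
fittedPair <- local({
  cache <- NULL
  function(nFaces = 400, nRaters = 20, cosAngle = -0.4, seed = 11) {
    key <- paste(nFaces, nRaters, cosAngle, seed)
    if (!is.null(cache) && cache$key == key) return(cache)
    truth <- makeGroundTruth(cosAngle = cosAngle, seed = seed)
    faces <- sampleFaces(nFaces, seed = seed + 1)
    simA <- simulateRatings(faces, truth, "attr", nRaters = nRaters,
                            seed = seed + 2)
    simM <- simulateRatings(faces, truth, "masc", nRaters = nRaters,
                            seed = seed + 3)
    attr <- scaleToSDUnits(fitTraitDirection(faces,
                                             standardizeScores(simA$matrix)))
    masc <- scaleToSDUnits(fitTraitDirection(faces,
                                             standardizeScores(simM$matrix)))
    cache <<- list(key = key, truth = truth, faces = faces, simA = simA,
                   simM = simM, attr = attr, masc = masc)
    cache
  }
})

# A TraitDirection built directly from a coefficient vector.
directionFromBeta <- function(beta, intercept = 0, name = "dir",
                              scaled = TRUE) {
  d <- new("TraitDirection", name = name, beta = beta, intercept = intercept,
           unitStep = numeric(0), scaled = FALSE, fittedOn = list(),
           orthogonalizedAgainst = NA_character_)
  if (scaled) d <- scaleToSDUnits(d)
  d
}

# Small long-format trial table generated from known fixed effects:
# rating = round(b0 + b1*level + b2*level^2 + participant + face + noise),
# clipped to 1..9. Crossed design: every participant rates every face at
# every level.
smallTrials <- function(nParticipants = 12, nFaces = 8, levels = -3:3,
                        b0 = 5, b1 = 0.8, b2 = -0.05, sdParticipant = 0.3,
                        sdFace = 0.2, sdResid = 0.5, seed = 1) {
  set.seed(seed)
  u <- rnorm(nParticipants, 0, sdParticipant)
  w <- rnorm(nFaces, 0, sdFace)
  g <- expand.grid(level_sd = levels, face = seq_len(nFaces),
                   participant = seq_len(nParticipants))
  lat <- b0 + b1 * g$level_sd + b2 * g$level_sd^2 + u[g$participant] +
    w[g$face] + rnorm(nrow(g), 0, sdResid)
  data.frame(
    participant_id = sprintf("p_%02d", g$participant),
    rater_sex = c("male", "female")[1 + g$participant %% 2],
    face_id = sprintf("f_%02d:dir:%+.1f", g$face, g$level_sd),
    face_sex = c("male", "female")[1 + g$face %% 2],
    task = "attractiveness",
    level_sd = g$level_sd,
    rating = as.integer(pmin(9, pmax(1, round(lat)))),
    stringsAsFactors = FALSE)
}

# Quick MCMC settings for desk-scale fits.
quickMcmc <- function(seed = 1, iterations = 2000, burnIn = 500, chains = 2) {
  mcmcControl(iterations, burnIn, chains, seed = seed)
}

# Integer rating matrix wrapped as a RatingMatrix with alternating sexes.
toyRatingMatrix <- function(v, task = "attractiveness") {
  RatingMatrix(v, faceSex = rep(c("male", "female"), length.out = nrow(v)),
               raterSex = rep(c("male", "female"), length.out = ncol(v)),
               task = task)
}
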