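test_that("sampleFaces draws a reproducible standard-normal population", {
  fs <- sampleFaces(400, seed = 51)
  expect_equal(nFaces(fs), 400L)
  expect_lt(max(abs(colMeans(faceCoords(fs)))), 0.2)
  expect_equal(sum(faceSex(fs) == "male"), 200L)

  again <- sampleFaces(400, seed = 51)
  expect_identical(faceCoords(again), faceCoords(fs))

  one <- sampleFaces(1, seed = 52)
  expect_equal(nFaces(one), 1L)
  expect_true(all(is.finite(faceCoords(one))))

  # the local seed does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(sampleFaces(5, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("makeGroundTruth hits the requested angle exactly", {
  t0 <- makeGroundTruth(cosAngle = 0, seed = 3)
  expect_lt(abs(sum(t0@betaAttr * t0@betaMasc)), 1e-8)

  t7 <- makeGroundTruth(cosAngle = -0.7, seed = 4)
  expect_equal(sum(t7@betaAttr * t7@betaMasc), -0.7, tolerance = 1e-8)
  expect_equal(sqrt(sum(t7@betaAttr^2)), 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(t7@betaMasc^2)), 1, tolerance = 1e-10)

  expect_error(makeGroundTruth(cosAngle = 1), "cosAngle")
  expect_error(makeGroundTruth(cosAngle = -1.2), "cosAngle")
})

test_that("simulateRatings follows the latent model", {
  faces <- sampleFaces(60, seed = 61)
  # noise-free limit: ratings are a deterministic monotone step function of
  # the true percept
  clean <- makeGroundTruth(cosAngle = -0.4, seed = 62, b2 = 0,
                           sdRaterIntercept = 0, sdRaterSlope = 0,
                           sdFace = 0, sdResid = 0)
  sim <- simulateRatings(faces, clean, "attr", nRaters = 3, seed = 63)
  v <- ratingValues(sim$matrix)
  expect_identical(v[, 1], v[, 2])
  s <- drop(faceCoords(faces) %*% clean@betaAttr)
  ord <- order(s)
  expect_true(all(diff(v[ord, 1]) >= 0))

  # clipping invariant at extreme gain
  loud <- makeGroundTruth(cosAngle = -0.4, seed = 64, likertGain = 5)
  simL <- simulateRatings(faces, loud, "masc", nRaters = 5, seed = 65)
  expect_true(all(ratingValues(simL$matrix) >= 1 &
                    ratingValues(simL$matrix) <= 9))

  # mean-rating slope on the true percept recovers b1 x likert gain
  quiet <- makeGroundTruth(cosAngle = -0.4, seed = 66, b2 = 0,
                           sdResid = 0.1, sdFace = 0, sdRaterIntercept = 0.1,
                           sdRaterSlope = 0.05)
  big <- sampleFaces(300, seed = 67)
  simQ <- simulateRatings(big, quiet, "attr", nRaters = 20, seed = 68)
  sQ <- drop(faceCoords(big) %*% quiet@betaAttr)
  slope <- coef(lm(rowMeans(ratingValues(simQ$matrix)) ~ sQ))[2]
  expect_lt(abs(slope - quiet@b1 * quiet@likertGain) /
              (quiet@b1 * quiet@likertGain), 0.1)

  # determinism of the full output
  simQ2 <- simulateRatings(big, quiet, "attr", nRaters = 20, seed = 68)
  expect_identical(simQ2$trials, simQ$trials)
})

test_that("simulated rating correlations propagate the true angle", {
  lowNoise <- makeGroundTruth(cosAngle = -0.4, seed = 71, b2 = 0,
                              sdRaterIntercept = 0.05, sdRaterSlope = 0.05,
                              sdFace = 0.05, sdResid = 0.1)
  faces <- sampleFaces(400, seed = 72)
  mA <- rowMeans(ratingValues(simulateRatings(faces, lowNoise, "attr",
                                              nRaters = 20, seed = 73)$matrix))
  mM <- rowMeans(ratingValues(simulateRatings(faces, lowNoise, "masc",
                                              nRaters = 20, seed = 74)$matrix))
  r <- cor(mA, mM)
  expect_lt(r, 0)
  expect_lt(abs(abs(r) - 0.4), 0.15)
})

test_that("simulateExperiment2 reproduces the validation design", {
  pair <- fittedPair()
  e2 <- simulateExperiment2(pair$truth, pair$attr, pair$masc,
                            simConfig("exp2_attr_orth", seed = 81))
  expect_equal(nFaces(e2$stimuli$attr_orth) + nFaces(e2$stimuli$sexdim_orth),
               280L)
  meta <- parseTransformedIds(faceIds(e2$stimuli$attr_orth))
  expect_equal(sort(unique(meta$level)), -3:3)
  expect_equal(nrow(e2$trials), 4 * 16 * 140)
  # between-subjects: each participant appears in exactly one task x
  # transformation cell
  cellPer <- tapply(paste(e2$trials$task, e2$trials$transform),
                    e2$trials$participant_id, function(x) length(unique(x)))
  expect_true(all(cellPer == 1))

  # zero estimation error: nuisance-task mean ratings are level-invariant
  # up to noise (each per-level mean within 3 MC standard errors)
  trueAttr <- directionFromBeta(pair$truth@betaAttr, name = "attr")
  trueMasc <- directionFromBeta(pair$truth@betaMasc, name = "masc")
  e2t <- simulateExperiment2(pair$truth, trueAttr, trueMasc,
                             simConfig("exp2_attr_orth", seed = 82))
  nuis <- e2t$trials[e2t$trials$transform == "attr_orth" &
                       e2t$trials$task == "sexual_dimorphism", ]
  grand <- mean(nuis$rating)
  for (lv in unique(nuis$level_sd)) {
    x <- nuis$rating[nuis$level_sd == lv]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - grand), 3 * se + 0.05)
  }
})

test_that("recoveryReport quantifies direction recovery", {
  truth <- makeGroundTruth(cosAngle = -0.4, seed = 91)
  exact <- directionFromBeta(truth@betaAttr)
  r <- recoveryReport(truth, exact, "attr")
  expect_equal(r$cosine, 1.0, tolerance = 1e-12)
  expect_equal(r$scaleError, 0, tolerance = 1e-10)

  flipped <- directionFromBeta(-truth@betaAttr)
  expect_equal(recoveryReport(truth, flipped, "attr")$cosine, -1.0,
               tolerance = 1e-12)

  # full pipeline at study scale recovers both directions well
  pair <- fittedPair()
  expect_gte(recoveryReport(pair$truth, pair$attr, "attr")$cosine, 0.9)
  expect_gte(recoveryReport(pair$truth, pair$masc, "masc")$cosine, 0.9)
})
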