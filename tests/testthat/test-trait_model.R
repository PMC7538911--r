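test_that("standardizeScores averages raters then z-scores across faces", {
  v <- cbind(c(1L, 4L, 7L), c(3L, 6L, 9L))  # rater means (2, 5, 8)
  rm <- toyRatingMatrix(v)
  z <- scoreValues(standardizeScores(rm))
  expect_equal(unname(z), c(-1, 0, 1))  # sample SD of (2,5,8) is 3

  # degenerate: all faces share the same mean
  same <- toyRatingMatrix(cbind(c(2L, 2L, 2L), c(6L, 6L, 6L)))
  expect_error(standardizeScores(same), "zero variance")

  # invariant holds by construction on random matrices
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(sample(1:9, 40, replace = TRUE), 8, 5)
    z <- scoreValues(standardizeScores(toyRatingMatrix(m)))
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("RatingMatrix rejects out-of-scale or tiny inputs", {
  expect_error(toyRatingMatrix(matrix(c(0L, 5L, 5L, 5L), 2, 2)), "\\[1, 9\\]")
  expect_error(toyRatingMatrix(matrix(5L, 1, 3)), "at least 2")
})

test_that("fitTraitDirection matches the normal-equations oracle", {
  set.seed(7)
  n <- 150
  X <- matrix(rnorm(n * 100), n, 100)
  betaTrue <- rnorm(100) / 10
  yExact <- drop(X %*% betaTrue)
  yExact <- (yExact - mean(yExact)) / sd(yExact)
  faces <- FaceSet(X, rep(c("male", "female"), length.out = n))
  sc <- new("StandardizedScores", score = setNames(yExact, faceIds(faces)),
            task = "attractiveness", nRaters = 1L,
            faceSex = unname(faceSex(faces)))

  # noise-free recovery: fitted beta reproduces the generating projection
  fit <- fitTraitDirection(faces, sc)
  expect_equal(predictScore(fit, faces), sc@score, tolerance = 1e-8)

  # brute-force oracle: solve the normal equations directly
  A <- cbind(1, X)
  co <- solve(t(A) %*% A, t(A) %*% yExact)
  expect_equal(fit@intercept, co[1], tolerance = 1e-8)
  expect_equal(fit@beta, co[-1], tolerance = 1e-8)

  # residuals orthogonal to every coordinate column
  res <- sc@score - predictScore(fit, faces)
  expect_lt(max(abs(t(X) %*% res)) / max(abs(sc@score)), 1e-8)

  # pure-noise scores: every coefficient small (5 / sqrt(n) bound), and the
  # fit still agrees with the oracle on the same data
  set.seed(8)
  nn <- 400
  Xn <- matrix(rnorm(nn * 100), nn, 100)
  yn <- rnorm(nn); yn <- (yn - mean(yn)) / sd(yn)
  facesN <- FaceSet(Xn, rep(c("male", "female"), length.out = nn))
  scN <- new("StandardizedScores", score = setNames(yn, faceIds(facesN)),
             task = "attractiveness", nRaters = 1L,
             faceSex = unname(faceSex(facesN)))
  fitN <- fitTraitDirection(facesN, scN)
  expect_lt(max(abs(fitN@beta)), 5 / sqrt(nn))
  An <- cbind(1, Xn)
  coN <- solve(t(An) %*% An, t(An) %*% yn)
  expect_equal(fitN@beta, coN[-1], tolerance = 1e-8)

  # R^2 of predictions matches the least-squares oracle
  r2Oracle <- 1 - sum((yn - An %*% coN)^2) / sum((yn - mean(yn))^2)
  expect_equal(cor(predictScore(fitN, facesN), yn)^2, r2Oracle,
               tolerance = 1e-8)
})

test_that("fitTraitDirection enforces its preconditions", {
  pair <- fittedPair()
  few <- sampleFaces(50, seed = 3)
  sim <- simulateRatings(few, pair$truth, "attr", nRaters = 4, seed = 5)
  sc <- standardizeScores(sim$matrix)
  expect_error(fitTraitDirection(few, sc), "underdetermined")

  scBad <- standardizeScores(pair$simA$matrix)
  expect_error(fitTraitDirection(few, scBad), "ids")
})

test_that("per-face-sex policy fits each sex separately", {
  pair <- fittedPair()
  sc <- standardizeScores(pair$simA$matrix)
  both <- fitTraitDirection(pair$faces, sc, sexPolicy = "per_face_sex")
  expect_named(both, c("male", "female"))
  expect_equal(both$male@fittedOn$n_faces, 200)
  # each sex-specific fit interpolates its own subset better than the pooled
  pooled <- fitTraitDirection(pair$faces, sc)
  maleIds <- names(faceSex(pair$faces))[faceSex(pair$faces) == "male"]
  resM <- scoreValues(sc)[maleIds] -
    predictScore(both$male, pair$faces[maleIds])
  resP <- scoreValues(sc)[maleIds] -
    predictScore(pooled, pair$faces[maleIds])
  expect_lte(sum(resM^2), sum(resP^2) + 1e-10)
})

test_that("scaleToSDUnits gives a unit predicted-score step", {
  beta <- numeric(100); beta[1] <- 2
  d <- directionFromBeta(beta, intercept = 0.3, scaled = FALSE)
  s <- scaleToSDUnits(d)
  expect_equal(s@unitStep[1], 0.5)
  expect_equal(s@unitStep[-1], numeric(99))

  # algebraic identity on random faces and directions
  set.seed(12)
  for (i in 1:5) {
    d <- directionFromBeta(rnorm(100), intercept = rnorm(1))
    x <- rnorm(100)
    expect_equal(predictScore(d, x + d@unitStep) - predictScore(d, x), 1,
                 tolerance = 1e-10)
    # composition: transforming at level +3 raises the score by 3
    expect_equal(predictScore(d, x + 3 * d@unitStep) - predictScore(d, x), 3,
                 tolerance = 1e-9)
  }

  zero <- new("TraitDirection", name = "z", beta = numeric(0), intercept = 0,
              unitStep = numeric(0), scaled = FALSE, fittedOn = list(),
              orthogonalizedAgainst = NA_character_)
  expect_error(scaleToSDUnits(zero), "degenerate")
})

test_that("orthogonalize matches hand Gram-Schmidt and dissociates scores", {
  # two active dimensions, solved by hand: (1,1) minus its projection on
  # (0,1) leaves (1,0)
  bt <- numeric(100); bt[1:2] <- 1
  bn <- numeric(100); bn[2] <- 1
  target <- directionFromBeta(bt, name = "t")
  nuis <- directionFromBeta(bn, name = "n")
  orth <- orthogonalize(target, nuis)
  expect_equal(orth@beta[1], 1)
  expect_equal(orth@beta[-1], numeric(99))
  expect_identical(orth@orthogonalizedAgainst, "n")

  # already-orthogonal target is unchanged up to the rescaling
  bo <- numeric(100); bo[3] <- 2
  ortho0 <- orthogonalize(directionFromBeta(bo), nuis)
  expect_equal(ortho0@beta, bo, tolerance = 1e-12)

  # self-orthogonalization is degenerate
  expect_error(orthogonalize(target, target), "parallel")

  # fitted pair: exact dissociation identity and target preservation
  pair <- fittedPair()
  attrOrth <- orthogonalize(pair$attr, pair$masc)
  expect_lt(abs(sum(attrOrth@beta * pair$masc@beta)) /
              sqrt(sum(pair$masc@beta^2)), 1e-10)
  set.seed(21)
  x <- rnorm(100)
  for (k in c(-3, -1, 0.5, 2)) {
    moved <- x + k * unitStep(attrOrth)
    expect_equal(predictScore(pair$masc, moved), predictScore(pair$masc, x),
                 tolerance = 1e-10)
    expect_equal(predictScore(attrOrth, moved) - predictScore(attrOrth, x),
                 k, tolerance = 1e-8)
  }

  # idempotence
  again <- orthogonalize(attrOrth, pair$masc)
  relChange <- sqrt(sum((again@beta - attrOrth@beta)^2)) /
    sqrt(sum(attrOrth@beta^2))
  expect_lt(relChange, 1e-10)
})

test_that("predictScore is affine in the coordinates", {
  d <- directionFromBeta(rnorm(100), intercept = 0.7)
  expect_equal(predictScore(d, numeric(100)), 0.7)
  d0 <- directionFromBeta(d@beta, intercept = 0)
  set.seed(2)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(predictScore(d0, x + y),
               predictScore(d0, x) + predictScore(d0, y), tolerance = 1e-10)
})

test_that("direction artifacts round-trip through JSON", {
  pair <- fittedPair()
  orth <- orthogonalize(pair$attr, pair$masc)
  path <- withr::local_tempfile(fileext = ".json")
  writeTraitDirection(orth, path)
  back <- readTraitDirection(path)
  expect_equal(back@beta, orth@beta, tolerance = 1e-14)
  expect_equal(back@unitStep, orth@unitStep, tolerance = 1e-14)
  expect_identical(back@scaled, TRUE)
  expect_identical(back@orthogonalizedAgainst, orth@orthogonalizedAgainst)
})

test_that("trial tables round-trip and pivot into rating matrices", {
  pair <- fittedPair(nFaces = 400)
  trials <- pair$simA$trials
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrials(trials, path)
  back <- readTrials(path)
  expect_equal(back$rating, trials$rating)
  rmBack <- trialsToRatingMatrix(back)
  expect_equal(ratingValues(rmBack)[faceIds(pair$simA$matrix),
                                    colnames(ratingValues(pair$simA$matrix))],
               ratingValues(pair$simA$matrix))
  bad <- trials; bad$rating[1] <- 12
  expect_error(writeTrials(bad, path), "\\[1, 9\\]")
})
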