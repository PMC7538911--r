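test_that("sampler defaults follow the full estimation settings", {
  mc <- mcmcControl()
  expect_identical(mc$iterations, 13000L)
  expect_identical(mc$burnIn, 3000L)
  expect_identical(mc$chains, 4L)
})

test_that("modelSpec enforces term hierarchy", {
  expect_error(modelSpec(c("level2")), "linear")
  expect_error(modelSpec(c("level", "level:face_sex")), "main effects")
  expect_error(modelSpec("level", randomParticipant = "level"), "intercept")
  expect_silent(validObject(modelSpec(c("level", "level2", "face_sex",
                                        "level:face_sex"))))
  expect_length(candidateModelSpecs(), 8L)
  ms <- maximalRandomStructure(c("level", "level2", "face_sex", "rater_sex",
                                 "level:face_sex"))
  expect_true("intercept" %in% ms$participant)
  expect_false("rater_sex" %in% ms$participant)
  expect_true("rater_sex" %in% ms$face)
})

test_that("fitHierarchical recovers known generating fixed effects", {
  trials <- smallTrials(nParticipants = 16, nFaces = 10, b1 = 0.8,
                        b2 = -0.05, seed = 101)
  fit <- fitHierarchical(trials, modelSpec(c("level", "level2")),
                         quickMcmc(seed = 7))
  s <- posteriorSummary(fit)
  lin <- s[s$parameter == "level", ]
  quad <- s[s$parameter == "level2", ]
  expect_true(lin$CrI_low <= 0.8 && 0.8 <= lin$CrI_high)
  expect_true(quad$CrI_low <= -0.05 && -0.05 <= quad$CrI_high)
  expect_true(lin$CrI_low > 0)  # strong effect detected
  expect_true(all(s$Rhat < 1.01, na.rm = TRUE))
  expect_true(all(s$CrI_low <= s$EAP & s$EAP <= s$CrI_high))

  # null linear effect: CrI contains zero
  null <- smallTrials(nParticipants = 10, nFaces = 6, b1 = 0, b2 = 0,
                      seed = 103)
  fit0 <- fitHierarchical(null, modelSpec("level"), quickMcmc(seed = 9,
                                                              iterations = 1500))
  l0 <- posteriorSummary(fit0)
  l0 <- l0[l0$parameter == "level", ]
  expect_true(l0$CrI_low <= 0 && 0 <= l0$CrI_high)
})

test_that("fitHierarchical validates its inputs before sampling", {
  trials <- smallTrials(nParticipants = 4, nFaces = 4, seed = 5)
  oneLevel <- trials[trials$level_sd == 1, ]
  expect_error(fitHierarchical(oneLevel, modelSpec("level"), quickMcmc()),
               "distinct")
  # a random slope for a term without variation is caught up front
  allMale <- trials
  allMale$rater_sex <- "male"
  expect_error(
    fitHierarchical(allMale,
                    modelSpec(c("level", "rater_sex"),
                              randomParticipant = c("intercept", "rater_sex")),
                    quickMcmc()),
    "rank|single level")
})

test_that("WAIC matches a hand-computed table and orders models sensibly", {
  # fixed 4-draw x 3-observation log-likelihood table, formula by hand
  ll <- matrix(log(c(0.2, 0.3, 0.25, 0.22,
                     0.10, 0.12, 0.08, 0.11,
                     0.30, 0.28, 0.33, 0.27)), nrow = 4)
  lppd <- sum(log(colMeans(exp(ll))))
  pW <- sum(apply(ll, 2, var))
  expect_equal(as.numeric(waicFromLogLik(ll)), -2 * (lppd - pW),
               tolerance = 1e-10)

  # identical draws give identical WAIC, and the generating model beats an
  # over-simplified one on strong-effect data
  trials <- smallTrials(nParticipants = 12, nFaces = 8, b1 = 0.9, b2 = -0.3,
                        seed = 107)
  mc <- quickMcmc(seed = 11, iterations = 1500)
  fitFull <- fitHierarchical(trials, modelSpec(c("level", "level2")), mc)
  fitLin <- fitHierarchical(trials, modelSpec("level"), mc)
  expect_identical(as.numeric(waic(fitFull)), as.numeric(waic(fitFull)))
  expect_lt(as.numeric(waic(fitFull)), as.numeric(waic(fitLin)))

  noLL <- fitHierarchical(trials[trials$participant_id %in%
                                   sprintf("p_%02d", 1:4), ],
                          modelSpec("level"),
                          mcmcControl(800, 300, 1, seed = 3,
                                      retainLogLik = FALSE))
  expect_error(waic(noLL), "log-likelihood")
})

test_that("selectBest ranks candidates by WAIC with the best at the head", {
  trials <- smallTrials(nParticipants = 12, nFaces = 8, b1 = 0.9, b2 = -0.3,
                        seed = 109)
  cands <- list(modelSpec("level"), modelSpec(c("level", "level2")))
  cmp <- selectBest(trials, cands, quickMcmc(seed = 13, iterations = 1500))
  expect_equal(nrow(cmp@ladder), 2L)
  expect_false(is.unsorted(cmp@ladder$WAIC))
  expect_identical(cmp@best, cmp@ladder$model[1])
  expect_true(grepl("Q", cmp@best))  # strong quadratic data
  expect_true(all(is.finite(cmp@ladder$WAIC)))
  expect_s4_class(bestFit(cmp), "PosteriorSummary")
})

test_that("generatedQuantities forms draw-wise coefficient differences", {
  trials1 <- smallTrials(nParticipants = 10, nFaces = 6, b1 = 0.6, b2 = 0,
                         seed = 113)
  trials0 <- smallTrials(nParticipants = 10, nFaces = 6, b1 = 0, b2 = 0,
                         seed = 114)
  mc <- quickMcmc(seed = 17, iterations = 1500)
  fitA <- fitHierarchical(trials1, modelSpec("level"), mc)
  fitB <- fitHierarchical(trials0, modelSpec("level"), mc)

  same <- generatedQuantities(fitA, fitA, "level")
  expect_lt(abs(same@summary$EAP), 1e-12)

  gq <- generatedQuantities(fitA, fitB, "level")
  expect_true(gq@summary$CrI_low <= 0.6 && 0.6 <= gq@summary$CrI_high)
  expect_gt(gq@summary$CrI_low, 0)

  swapped <- generatedQuantities(fitB, fitA, "level")
  expect_equal(swapped@summary$EAP, -gq@summary$EAP, tolerance = 1e-12)

  expect_error(generatedQuantities(fitA, fitB, "level2"), "not retained")
})

test_that("credible intervals attain near-nominal coverage over replicates", {
  # 20 seeded replicates of a small design with a known linear effect;
  # the 95% CrI should cover the generating value in at least 17
  b1 <- 0.7
  covered <- 0L
  for (r in 1:20) {
    trials <- smallTrials(nParticipants = 6, nFaces = 4, b1 = b1, b2 = 0,
                          sdResid = 0.6, seed = 200 + r)
    fit <- suppressWarnings(
      fitHierarchical(trials, modelSpec("level"),
                      mcmcControl(1200, 400, 2, seed = 300 + r)))
    s <- posteriorSummary(fit)
    s <- s[s$parameter == "level", ]
    if (s$CrI_low <= b1 && b1 <= s$CrI_high) covered <- covered + 1L
  }
  expect_gte(covered, 17L)
})

test_that("rescaling the level axis rescales the slope and preserves WAIC", {
  trials <- smallTrials(nParticipants = 12, nFaces = 8, b1 = 0.8, b2 = 0,
                        seed = 211)
  mc <- quickMcmc(seed = 19, iterations = 1500)
  fit1 <- fitHierarchical(trials, modelSpec("level"), mc)
  trials2 <- trials
  trials2$level_sd <- trials2$level_sd * 2
  fit2 <- fitHierarchical(trials2, modelSpec("level"), mc)
  e1 <- posteriorSummary(fit1); e1 <- e1$EAP[e1$parameter == "level"]
  e2 <- posteriorSummary(fit2); e2 <- e2$EAP[e2$parameter == "level"]
  expect_equal(2 * e2, e1, tolerance = 0.05)
  expect_lt(abs(as.numeric(waic(fit1)) - as.numeric(waic(fit2))), 5)
})
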