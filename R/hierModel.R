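#' @include AllClasses.R traitModel.R
NULL

# ---- model specification ----------------------------------------------------

#' Construct a ModelSpec for the hierarchical rating regression
#'
#' Fixed terms are drawn from \code{level}, \code{level2}, \code{face_sex},
#' \code{rater_sex} and the interactions \code{level:face_sex},
#' \code{level2:face_sex}, \code{level:rater_sex}, \code{level2:rater_sex}.
#' The linear \code{level} term is always present and the quadratic term is
#' never included without it. Sex factors are dummy-coded with male as the
#' reference, so \code{level} is the linear exaggeration slope for male faces
#' and \code{level:face_sex} the female-male slope difference.
#'
#' @param fixedTerms character vector of fixed-effect terms.
#' @param randomParticipant terms with by-participant random effects; must
#'   include \code{"intercept"}. Default: intercept and linear slope.
#' @param randomFace terms with by-face random effects (may be empty).
#' @param label short label for WAIC ladders (auto-generated if NULL).
#' @return a [ModelSpec-class]
#' @seealso [candidateModelSpecs()], [maximalRandomStructure()]
#' @export
modelSpec <- function(fixedTerms = c("level", "level2"),
                      randomParticipant = c("intercept", "level"),
                      randomFace = "intercept", label = NULL) {
  if (is.null(label)) {
    short <- c(level = "L", level2 = "Q", face_sex = "F", rater_sex = "R",
               `level:face_sex` = "LxF", `level2:face_sex` = "QxF",
               `level:rater_sex` = "LxR", `level2:rater_sex` = "QxR")
    label <- paste(short[fixedTerms], collapse = "+")
  }
  new("ModelSpec", fixedTerms = fixedTerms,
      randomParticipant = randomParticipant, randomFace = randomFace,
      label = label)
}

#' @export
setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec '%s'\n  fixed: %s\n  random (participant): %s\n  random (face): %s\n",
              object@label, paste(object@fixedTerms, collapse = ", "),
              paste(object@randomParticipant, collapse = ", "),
              if (length(object@randomFace))
                paste(object@randomFace, collapse = ", ") else "none"))
})

#' The maximal random-effect structure for a set of fixed terms
#'
#' By-participant intercepts and slopes for every fixed term that varies
#' within participants (all level terms, face sex and their interactions) and
#' by-face intercepts and slopes for terms varying within faces (rater sex
#' terms) — the "maximal structure justified by the design" convention.
#'
#' @param fixedTerms character vector of fixed terms.
#' @return list with elements \code{participant} and \code{face}.
#' @export
maximalRandomStructure <- function(fixedTerms) {
  withinParticipant <- setdiff(fixedTerms,
                               c("rater_sex"))  # rater sex is between-participant
  withinFace <- intersect(fixedTerms,
                          c("rater_sex", "level:rater_sex", "level2:rater_sex"))
  list(participant = c("intercept", withinParticipant),
       face = c("intercept", withinFace))
}

#' Candidate model lattice for WAIC selection
#'
#' All combinations of (i) the quadratic level term, (ii) the face-sex block
#' (main effect plus its interactions with the included level terms) and
#' (iii) the rater-sex block, always containing the linear level term:
#' 8 candidates.
#'
#' @param randomParticipant,randomFace random structure applied to every
#'   candidate (see [modelSpec()]).
#' @return list of [ModelSpec-class] objects
#' @export
candidateModelSpecs <- function(randomParticipant = c("intercept", "level"),
                                randomFace = "intercept") {
  specs <- list()
  for (quad in c(FALSE, TRUE)) for (fs in c(FALSE, TRUE)) for (rs in c(FALSE, TRUE)) {
    ft <- "level"
    if (quad) ft <- c(ft, "level2")
    if (fs) {
      ft <- c(ft, "face_sex", "level:face_sex")
      if (quad) ft <- c(ft, "level2:face_sex")
    }
    if (rs) {
      ft <- c(ft, "rater_sex", "level:rater_sex")
      if (quad) ft <- c(ft, "level2:rater_sex")
    }
    specs[[length(specs) + 1]] <- modelSpec(ft, randomParticipant, randomFace)
  }
  specs
}

#' MCMC sampler settings
#'
#' Defaults follow the full estimation settings (13,000 iterations of which
#' 3,000 are burn-in, 4 chains); pass smaller values for desk-scale runs.
#'
#' @param iterations total iterations per chain (including burn-in).
#' @param burnIn burn-in iterations discarded per chain.
#' @param chains number of chains.
#' @param seed integer seed; chain RNGs are derived from it.
#' @param thin keep every \code{thin}-th draw.
#' @param retainLogLik retain pointwise log-likelihood draws (needed for
#'   [waic()]; switch off to save memory).
#' @return list of settings for [fitHierarchical()]
#' @export
mcmcControl <- function(iterations = 13000, burnIn = 3000, chains = 4,
                        seed = 1, thin = 1, retainLogLik = TRUE) {
  stopifnot(iterations > burnIn, chains >= 1, thin >= 1)
  list(iterations = as.integer(iterations), burnIn = as.integer(burnIn),
       chains = as.integer(chains), seed = as.integer(seed),
       thin = as.integer(thin), retainLogLik = isTRUE(retainLogLik))
}

# ---- design matrices --------------------------------------------------------

# Map spec terms to design columns (dummy coding, male reference).
.termColumn <- function(term, df) {
  switch(term,
    level = df$level_sd,
    level2 = df$level_sd^2,
    face_sex = as.numeric(df$face_sex == "female"),
    rater_sex = as.numeric(df$rater_sex == "female"),
    `level:face_sex` = df$level_sd * (df$face_sex == "female"),
    `level2:face_sex` = df$level_sd^2 * (df$face_sex == "female"),
    `level:rater_sex` = df$level_sd * (df$rater_sex == "female"),
    `level2:rater_sex` = df$level_sd^2 * (df$rater_sex == "female"),
    stopf("unknown model term: %s", term))
}

.termLabel <- function(term) {
  c(level = "level", level2 = "level2", face_sex = "face_sexF",
    rater_sex = "rater_sexF", `level:face_sex` = "level:face_sexF",
    `level2:face_sex` = "level2:face_sexF",
    `level:rater_sex` = "level:rater_sexF",
    `level2:rater_sex` = "level2:rater_sexF")[[term]]
}

.designMatrix <- function(terms, df, intercept = TRUE) {
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, nrow(df))
  for (t in setdiff(terms, "intercept"))
    cols[[.termLabel(t)]] <- .termColumn(t, df)
  do.call(cbind, cols)
}

# ---- JAGS model generation --------------------------------------------------

# Build JAGS code for a Gaussian mixed model with optional by-participant and
# by-face multivariate-normal random effects. Priors: normal(0, 5) fixed
# effects, half-t(3, 0, 2.5) scales, Wishart(I, K+1) on random-effect
# precision matrices (marginally uniform correlations).
.jagsCode <- function(Kp, Kf) {
  lik <- c("model {", "for (i in 1:N) {")
  muTerms <- "inprod(X[i, ], beta[])"
  if (Kp == 1) muTerms <- c(muTerms, "Zp[i, 1] * u1[pid[i]]")
  if (Kp > 1) muTerms <- c(muTerms, "inprod(Zp[i, ], u[pid[i], ])")
  if (Kf == 1) muTerms <- c(muTerms, "Zf[i, 1] * w1[fid[i]]")
  if (Kf > 1) muTerms <- c(muTerms, "inprod(Zf[i, ], w[fid[i], ])")
  lik <- c(lik,
           paste0("mu[i] <- ", paste(muTerms, collapse = " + ")),
           "y[i] ~ dnorm(mu[i], tauResid)", "}")
  fx <- c("for (j in 1:P) { beta[j] ~ dnorm(0, 0.04) }",
          "sigma ~ dt(0, pow(2.5, -2), 3) T(0,)",
          "tauResid <- pow(sigma, -2)")
  re <- character(0)
  if (Kp == 1) re <- c(re,
    "for (p in 1:Np) { u1[p] ~ dnorm(0, pow(sdU[1], -2)) }",
    "sdU[1] ~ dt(0, pow(2.5, -2), 3) T(0,)")
  if (Kp > 1) re <- c(re,
    "for (p in 1:Np) { u[p, 1:Kp] ~ dmnorm(zeroP[1:Kp], TauU[1:Kp, 1:Kp]) }",
    "TauU[1:Kp, 1:Kp] ~ dwish(Ip[1:Kp, 1:Kp], KpDf)",
    "SigmaU[1:Kp, 1:Kp] <- inverse(TauU[1:Kp, 1:Kp])",
    "for (k in 1:Kp) { sdU[k] <- sqrt(SigmaU[k, k]) }")
  if (Kf == 1) re <- c(re,
    "for (f in 1:Nf) { w1[f] ~ dnorm(0, pow(sdW[1], -2)) }",
    "sdW[1] ~ dt(0, pow(2.5, -2), 3) T(0,)")
  if (Kf > 1) re <- c(re,
    "for (f in 1:Nf) { w[f, 1:Kf] ~ dmnorm(zeroF[1:Kf], TauW[1:Kf, 1:Kf]) }",
    "TauW[1:Kf, 1:Kf] ~ dwish(If[1:Kf, 1:Kf], KfDf)",
    "SigmaW[1:Kf, 1:Kf] <- inverse(TauW[1:Kf, 1:Kf])",
    "for (k in 1:Kf) { sdW[k] <- sqrt(SigmaW[k, k]) }")
  paste(c(lik, fx, re, "}"), collapse = "\n")
}

# ---- fitting ----------------------------------------------------------------

#' Fit a hierarchical Bayesian regression of ratings on face exaggeration
#'
#' Gaussian-likelihood mixed model of Likert ratings on the exaggeration
#' level (linear and optionally quadratic), face sex and rater sex, with
#' by-participant and by-face random intercepts and slopes, sampled by MCMC.
#' Posterior summaries report the EAP (posterior mean), central 95\%
#' credible interval and the Gelman-Rubin Rhat for every monitored
#' parameter; a warning is emitted when any Rhat exceeds 1.01.
#'
#' @param data long-format trial data.frame (see [readTrials()]).
#' @param spec a [ModelSpec-class].
#' @param mcmc sampler settings from [mcmcControl()].
#' @return a [PosteriorSummary-class] with retained fixed-effect draws and
#'   (unless disabled) pointwise log-likelihood draws for [waic()].
#' @examples
#' \dontrun{
#' fit <- fitHierarchical(trials, modelSpec(c("level", "level2")),
#'                        mcmcControl(2000, 500, 2, seed = 7))
#' posteriorSummary(fit)
#' }
#' @export
fitHierarchical <- function(data, spec, mcmc = mcmcControl()) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  validateTrials(data)
  if (length(unique(data$participant_id)) < 2)
    stopf("need at least 2 participants")
  if (length(unique(data$face_id)) < 2)
    stopf("need at least 2 faces")
  if (length(unique(data$level_sd)) < 2)
    stopf("need at least 2 distinct exaggeration levels")

  X <- .designMatrix(spec@fixedTerms, data)
  if (qr(X)$rank < ncol(X))
    stopf("non-identifiable specification: fixed-effect design is rank-deficient")
  for (t in setdiff(spec@randomParticipant, "intercept"))
    if (length(unique(.termColumn(t, data))) < 2)
      stopf("non-identifiable specification: random slope for '%s' has a single level", t)
  Zp <- .designMatrix(spec@randomParticipant, data,
                      intercept = "intercept" %in% spec@randomParticipant)
  Zf <- if (length(spec@randomFace))
    .designMatrix(spec@randomFace, data,
                  intercept = "intercept" %in% spec@randomFace) else NULL
  Kp <- ncol(Zp)
  Kf <- if (is.null(Zf)) 0L else ncol(Zf)

  pid <- as.integer(factor(data$participant_id))
  fid <- as.integer(factor(data$face_id))
  y <- as.numeric(data$rating)
  jd <- list(N = length(y), P = ncol(X), X = X, y = y,
             pid = pid, Np = max(pid), Zp = Zp)
  if (Kp > 1) {
    jd$Kp <- Kp; jd$zeroP <- rep(0, Kp); jd$Ip <- diag(Kp); jd$KpDf <- Kp + 1
  }
  if (Kf >= 1) { jd$fid <- fid; jd$Nf <- max(fid); jd$Zf <- Zf }
  if (Kf > 1) {
    jd$Kf <- Kf; jd$zeroF <- rep(0, Kf); jd$If <- diag(Kf); jd$KfDf <- Kf + 1
  }

  inits <- lapply(seq_len(mcmc$chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = childSeed(mcmc$seed, paste0("chain", c))))
  monitors <- c("beta", "sigma", "sdU")
  if (Kp > 1) monitors <- c(monitors, "SigmaU")
  if (Kf >= 1) monitors <- c(monitors, "sdW")
  if (Kf > 1) monitors <- c(monitors, "SigmaW")
  if (mcmc$retainLogLik) monitors <- c(monitors, "mu")

  # block-samples the Gaussian linear part; essential for mixing of
  # correlated design columns (level^2, sex dummies)
  rjags::load.module("glm", quiet = TRUE)
  model <- rjags::jags.model(textConnection(.jagsCode(Kp, Kf)), data = jd,
                             inits = inits, n.chains = mcmc$chains,
                             quiet = TRUE)
  update(model, mcmc$burnIn, progress.bar = "none")
  keep <- mcmc$iterations - mcmc$burnIn
  samp <- rjags::coda.samples(model, monitors, n.iter = keep,
                              thin = mcmc$thin, progress.bar = "none")

  fixedNames <- colnames(X)
  renameMap <- c(stats::setNames(fixedNames, sprintf("beta[%d]", seq_along(fixedNames))),
                 sigma = "sigma")
  pTerms <- c(if ("intercept" %in% spec@randomParticipant) "(Intercept)",
              vapply(setdiff(spec@randomParticipant, "intercept"), .termLabel, ""))
  for (k in seq_len(Kp))
    renameMap[sprintf("sdU[%d]", k)] <- sprintf("sd_participant_%s", pTerms[k])
  if (Kf >= 1) {
    fTerms <- c(if ("intercept" %in% spec@randomFace) "(Intercept)",
                vapply(setdiff(spec@randomFace, "intercept"), .termLabel, ""))
    for (k in seq_len(Kf))
      renameMap[sprintf("sdW[%d]", k)] <- sprintf("sd_face_%s", fTerms[k])
  }
  if (Kp > 1)
    for (a in seq_len(Kp - 1)) for (b in (a + 1):Kp)
      renameMap[sprintf("SigmaU[%d,%d]", a, b)] <-
        sprintf("cov_participant_%s__%s", pTerms[a], pTerms[b])
  if (Kf > 1)
    for (a in seq_len(Kf - 1)) for (b in (a + 1):Kf)
      renameMap[sprintf("SigmaW[%d,%d]", a, b)] <-
        sprintf("cov_face_%s__%s", fTerms[a], fTerms[b])

  full <- do.call(rbind, lapply(samp, as.matrix))
  isMu <- grepl("^mu\\[", colnames(full))
  logLik <- matrix(numeric(0), 0, 0)
  if (mcmc$retainLogLik) {
    muD <- full[, isMu, drop = FALSE]
    ord <- order(as.integer(sub("^mu\\[(\\d+)\\]$", "\\1", colnames(muD))))
    muD <- muD[, ord, drop = FALSE]
    logLik <- stats::dnorm(matrix(y, nrow(muD), length(y), byrow = TRUE),
                           muD, full[, "sigma"], log = TRUE)
  }
  keepCols <- colnames(full)[!isMu & colnames(full) %in% names(renameMap)]
  draws <- full[, keepCols, drop = FALSE]
  colnames(draws) <- renameMap[keepCols]

  # convert retained covariances to correlations for reporting
  corCols <- grep("^cov_", colnames(draws))
  for (cc in corCols) {
    nm <- colnames(draws)[cc]
    parts <- strsplit(sub("^cov_(participant|face)_", "", nm), "__")[[1]]
    grp <- sub("^cov_(participant|face)_.*", "\\1", nm)
    sdA <- draws[, sprintf("sd_%s_%s", grp, parts[1])]
    sdB <- draws[, sprintf("sd_%s_%s", grp, parts[2])]
    draws[, cc] <- draws[, cc] / (sdA * sdB)
    colnames(draws)[cc] <- sub("^cov_", "cor_", nm)
  }

  rhat <- rep(NA_real_, ncol(draws))
  names(rhat) <- colnames(draws)
  if (mcmc$chains >= 2) {
    per <- nrow(draws) / mcmc$chains
    blocks <- split(seq_len(nrow(draws)), rep(seq_len(mcmc$chains), each = per))
    for (j in seq_len(ncol(draws))) {
      ml <- coda::mcmc.list(lapply(blocks, function(ix) coda::mcmc(draws[ix, j])))
      rhat[j] <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE,
                                            multivariate = FALSE)$psrf[1, 1],
                          error = function(e) NA_real_)
    }
  }
  if (any(rhat > 1.01, na.rm = TRUE))
    warning(sprintf("Rhat > 1.01 for: %s",
                    paste(names(rhat)[which(rhat > 1.01)], collapse = ", ")),
            call. = FALSE)

  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975))
  summ <- data.frame(parameter = colnames(draws), EAP = colMeans(draws),
                     CrI_low = qs[1, ], CrI_high = qs[2, ], Rhat = rhat,
                     row.names = NULL)
  new("PosteriorSummary", summary = summ, draws = draws, logLik = logLik,
      mcmc = mcmc, spec = list(spec = spec),
      data = list(n = length(y), n_participants = max(pid),
                  n_faces = max(fid)))
}

#' @describeIn fitHierarchical summary table accessor
#' @param x a PosteriorSummary
#' @export
setMethod("posteriorSummary", "PosteriorSummary", function(x) x@summary)

#' @describeIn fitHierarchical retained draws accessor
#' @export
setMethod("posteriorDraws", "PosteriorSummary", function(x) x@draws)

#' @export
setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary: %d parameters, %d draws, %d observations\n",
              nrow(object@summary), nrow(object@draws), object@data$n %||% NA))
  fx <- object@summary[!grepl("^(sd_|cor_)", object@summary$parameter), ]
  print(format(fx, digits = 3), row.names = FALSE)
})

# ---- WAIC -------------------------------------------------------------------

#' WAIC from a pointwise log-likelihood matrix
#'
#' \eqn{WAIC = -2 (lppd - p_{WAIC})} with
#' \eqn{lppd = \sum_i \log \overline{\exp \ell_i}} (mean over draws) and
#' \eqn{p_{WAIC} = \sum_i \mathrm{var}(\ell_i)} over draws.
#'
#' @param logLik matrix, draws x observations, of log-likelihood values.
#' @return WAIC as a numeric scalar with attributes \code{lppd} and
#'   \code{pWaic}.
#' @export
waicFromLogLik <- function(logLik) {
  stopifnot(is.matrix(logLik), nrow(logLik) >= 2)
  lppd <- sum(apply(logLik, 2, logMeanExp))
  pW <- sum(apply(logLik, 2, stats::var))
  structure(-2 * (lppd - pW), lppd = lppd, pWaic = pW)
}

#' WAIC of a fitted hierarchical model
#'
#' @param fit a [PosteriorSummary-class] fitted with retained pointwise
#'   log-likelihood.
#' @return WAIC (numeric scalar; lower is better) with attributes
#'   \code{lppd} and \code{pWaic}.
#' @export
waic <- function(fit) {
  stopifnot(is(fit, "PosteriorSummary"))
  if (nrow(fit@logLik) == 0)
    stopf("fit has no retained pointwise log-likelihood; refit with retainLogLik = TRUE")
  waicFromLogLik(fit@logLik)
}

# ---- model selection --------------------------------------------------------

#' Fit candidate models and rank them by WAIC
#'
#' Fits every candidate [ModelSpec-class] to the same data and returns the
#' WAIC ladder sorted ascending, tagging the minimal-WAIC model as best.
#' Candidates that fail to fit are reported by label in the result's
#' \code{failures} slot (with a warning); at least one candidate must
#' succeed.
#'
#' @param data long-format trial data.frame.
#' @param candidates list of [ModelSpec-class] (e.g. [candidateModelSpecs()]).
#' @param mcmc sampler settings from [mcmcControl()]; each candidate gets a
#'   seed derived from it.
#' @return a [ModelComparison-class]
#' @export
selectBest <- function(data, candidates, mcmc = mcmcControl()) {
  stopifnot(length(candidates) >= 2)
  fits <- list()
  failures <- character(0)
  for (spec in candidates) {
    m <- mcmc
    m$seed <- childSeed(mcmc$seed, spec@label)
    res <- tryCatch(fitHierarchical(data, spec, m), error = function(e) e)
    if (inherits(res, "error")) {
      failures[spec@label] <- conditionMessage(res)
      warning(sprintf("candidate '%s' failed to fit: %s", spec@label,
                      conditionMessage(res)), call. = FALSE)
    } else fits[[spec@label]] <- res
  }
  if (!length(fits))
    stopf("all candidates failed to fit; first failure: %s", failures[1])
  w <- vapply(fits, function(f) as.numeric(waic(f)), 0)
  p <- vapply(fits, function(f) attr(waic(f), "pWaic"), 0)
  ladder <- data.frame(model = names(fits), WAIC = unname(w),
                       pWAIC = unname(p))
  ladder <- ladder[order(ladder$WAIC), ]
  rownames(ladder) <- NULL
  new("ModelComparison", ladder = ladder, best = ladder$model[1],
      fits = fits, failures = failures)
}

#' @export
setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison: %d candidates, best = '%s'\n",
              nrow(object@ladder), object@best))
  print(format(object@ladder, digits = 6), row.names = FALSE)
  if (length(object@failures))
    cat("failed:", paste(names(object@failures), collapse = ", "), "\n")
})

#' Best fitted model of a ModelComparison
#' @param x a ModelComparison
#' @return the [PosteriorSummary-class] of the minimal-WAIC candidate
#' @export
bestFit <- function(x) {
  stopifnot(is(x, "ModelComparison"))
  x@fits[[x@best]]
}

# ---- generated quantities ---------------------------------------------------

#' Draw-wise coefficient difference between two fitted models
#'
#' Samples the named coefficient from both posteriors and forms the
#' difference \code{a - b} draw by draw (the longer chain is truncated so
#' draw counts match), reporting its EAP and central 95\% credible interval
#' — the generated-quantity contrast used to compare the effect of face
#' exaggeration across transformations.
#'
#' @param fitA,fitB [PosteriorSummary-class] objects retaining draws for
#'   \code{term}.
#' @param term parameter name (e.g. \code{"level"}).
#' @return a [PosteriorSummary-class] holding the single derived parameter
#'   \code{delta_<term>}.
#' @export
generatedQuantities <- function(fitA, fitB, term) {
  stopifnot(is(fitA, "PosteriorSummary"), is(fitB, "PosteriorSummary"))
  for (f in list(fitA, fitB))
    if (!term %in% colnames(f@draws))
      stopf("term '%s' is not retained in both fits", term)
  a <- fitA@draws[, term]
  b <- fitB@draws[, term]
  n <- min(length(a), length(b))
  d <- a[seq_len(n)] - b[seq_len(n)]
  q <- unname(stats::quantile(d, c(0.025, 0.975)))
  summ <- data.frame(parameter = paste0("delta_", term), EAP = mean(d),
                     CrI_low = q[1], CrI_high = q[2], Rhat = NA_real_)
  new("PosteriorSummary", summary = summ,
      draws = matrix(d, ncol = 1,
                     dimnames = list(NULL, paste0("delta_", term))),
      logLik = matrix(numeric(0), 0, 0),
      mcmc = list(derived_from = c(nrow(fitA@draws), nrow(fitB@draws))),
      spec = list(), data = list(n = n))
}

#' Write a posterior summary (or WAIC ladder) as a delimited table
#'
#' @param x a [PosteriorSummary-class] or [ModelComparison-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeSummaryTable <- function(x, path) {
  if (is(x, "PosteriorSummary")) utils::write.csv(x@summary, path, row.names = FALSE)
  else if (is(x, "ModelComparison")) utils::write.csv(x@ladder, path, row.names = FALSE)
  else stopf("cannot write object of class %s", class(x)[1])
  invisible(path)
}
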