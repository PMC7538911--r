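#' @import methods
NULL

.FACE_DIM <- 100L
.FACE_SEXES <- c("male", "female")
.TASKS <- c("attractiveness", "sexual_dimorphism")

#' FaceSet: faces as points in the 100-dimensional face space
#'
#' A \code{FaceSet} holds an ordered collection of faces, each represented by
#' 100 coordinates (dimensions 1--50 are shape, 51--100 reflectance) in a
#' feature space whose origin is the average face of the generator population
#' and whose per-dimension unit is one population SD.
#'
#' @slot coords numeric matrix, faces x 100; rownames are face ids.
#' @slot faceSex character vector, one of \code{"male"}, \code{"female"} per face.
#' @slot provenance character scalar free-text metadata (source file, seed,
#'   transformation applied).
#'
#' @seealso [readFaces()], [writeFaces()], [transformFaces()], [sampleFaces()]
#' @export
setClass("FaceSet",
  representation(coords = "matrix", faceSex = "character",
                 provenance = "character"),
  prototype(coords = matrix(numeric(0), 0, 100,
                            dimnames = list(NULL, sprintf("dim_%03d", 1:100))),
            faceSex = character(0), provenance = ""))

setValidity("FaceSet", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != .FACE_DIM)
    msg <- c(msg, sprintf("coords must have %d columns, found %d",
                          .FACE_DIM, ncol(object@coords)))
  if (nrow(object@coords) > 0 && !all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  ids <- rownames(object@coords)
  if (nrow(object@coords) > 0 && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "face ids (rownames) must be present and unique")
  if (length(object@faceSex) != nrow(object@coords))
    msg <- c(msg, "faceSex must have one entry per face")
  if (length(object@faceSex) && !all(object@faceSex %in% .FACE_SEXES))
    msg <- c(msg, "faceSex entries must be 'male' or 'female'")
  if (length(msg)) msg else TRUE
})

#' TransformSpec: exaggeration levels for a face transformation
#'
#' @slot directionName name of the trait direction being applied.
#' @slot levels numeric vector of exaggeration levels in SD units, sorted
#'   ascending; default -3..+3 in unit steps (7 levels).
#'
#' @export
setClass("TransformSpec",
  representation(directionName = "character", levels = "numeric"),
  prototype(directionName = "trait", levels = -3:3))

setValidity("TransformSpec", function(object) {
  msg <- character(0)
  if (length(object@levels) == 0)
    msg <- c(msg, "levels must be non-empty")
  if (!all(is.finite(object@levels)))
    msg <- c(msg, "levels must be finite")
  if (is.unsorted(object@levels, strictly = TRUE))
    msg <- c(msg, "levels must be sorted strictly ascending")
  if (length(msg)) msg else TRUE
})

#' TraitDirection: a fitted perceptual dimension in face space
#'
#' The direction is the best linear fit of standardized ratings onto the 100
#' face coordinates: score = intercept + beta . coords. Once scaled
#' ([scaleToSDUnits()]), \code{unitStep} is the coordinate displacement that
#' raises the predicted standardized score by exactly 1 (one "SD unit" of
#' exaggeration).
#'
#' @slot name direction name, e.g. \code{"attractiveness"}.
#' @slot beta numeric(100) fitted coefficients.
#' @slot intercept numeric scalar.
#' @slot unitStep numeric(100) displacement per +1 SD level (length 0 until
#'   scaled).
#' @slot scaled logical; TRUE after [scaleToSDUnits()].
#' @slot fittedOn list of fit provenance (n_faces, task, sex_policy, seed).
#' @slot orthogonalizedAgainst name of the nuisance direction projected out,
#'   or NA.
#'
#' @seealso [fitTraitDirection()], [scaleToSDUnits()], [orthogonalize()],
#'   [predictScore()]
#' @export
setClass("TraitDirection",
  representation(name = "character", beta = "numeric", intercept = "numeric",
                 unitStep = "numeric", scaled = "logical", fittedOn = "list",
                 orthogonalizedAgainst = "character"),
  prototype(name = "trait", beta = numeric(0), intercept = 0,
            unitStep = numeric(0), scaled = FALSE, fittedOn = list(),
            orthogonalizedAgainst = NA_character_))

setValidity("TraitDirection", function(object) {
  msg <- character(0)
  if (length(object@beta) && length(object@beta) != .FACE_DIM)
    msg <- c(msg, sprintf("beta must have length %d", .FACE_DIM))
  if (length(object@beta) && !all(is.finite(object@beta)))
    msg <- c(msg, "beta must be finite")
  if (length(object@beta) && all(object@beta == 0))
    msg <- c(msg, "beta must not be identically zero")
  if (object@scaled) {
    if (length(object@unitStep) != .FACE_DIM)
      msg <- c(msg, "scaled direction must carry a unitStep of length 100")
    else if (abs(sum(object@beta * object@unitStep) - 1) > 1e-8)
      msg <- c(msg, "scaled direction must satisfy beta . unitStep == 1")
  }
  if (length(msg)) msg else TRUE
})

#' RatingMatrix: faces x raters Likert ratings for one task
#'
#' @slot values integer matrix (faces x raters) of ratings on the 1--9 scale;
#'   rownames face ids, colnames rater ids.
#' @slot faceSex per-face sex.
#' @slot raterSex per-rater sex.
#' @slot task \code{"attractiveness"} or \code{"sexual_dimorphism"}.
#'
#' @export
setClass("RatingMatrix",
  representation(values = "matrix", faceSex = "character",
                 raterSex = "character", task = "character"),
  prototype(task = "attractiveness"))

setValidity("RatingMatrix", function(object) {
  msg <- character(0)
  v <- object@values
  if (nrow(v) < 2 || ncol(v) < 2)
    msg <- c(msg, "need at least 2 faces and 2 raters")
  if (length(v) && (any(!is.finite(v)) || any(v < 1) || any(v > 9) ||
                    any(v != round(v))))
    msg <- c(msg, "all ratings must be integers in [1, 9]")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry face ids (rownames) and rater ids (colnames)")
  if (length(object@faceSex) != nrow(v))
    msg <- c(msg, "faceSex must have one entry per face")
  if (length(object@raterSex) != ncol(v))
    msg <- c(msg, "raterSex must have one entry per rater")
  if (!object@task %in% .TASKS)
    msg <- c(msg, "task must be 'attractiveness' or 'sexual_dimorphism'")
  if (length(msg)) msg else TRUE
})

#' StandardizedScores: per-face mean ratings, z-scored across faces
#'
#' @slot score named numeric vector (names = face ids), mean 0 and sample
#'   SD 1 across faces.
#' @slot task source rating task.
#' @slot nRaters number of raters averaged over.
#' @slot faceSex per-face sex, aligned with \code{score}.
#'
#' @export
setClass("StandardizedScores",
  representation(score = "numeric", task = "character", nRaters = "integer",
                 faceSex = "character"))

setValidity("StandardizedScores", function(object) {
  msg <- character(0)
  s <- object@score
  if (length(s) >= 2) {
    if (abs(mean(s)) > 1e-10) msg <- c(msg, "scores must have mean 0")
    if (abs(stats::sd(s) - 1) > 1e-10) msg <- c(msg, "scores must have sample SD 1")
  }
  if (is.null(names(s))) msg <- c(msg, "scores must be named by face id")
  if (length(object@faceSex) != length(s))
    msg <- c(msg, "faceSex must align with score")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: fixed and random structure of a hierarchical rating regression
#'
#' Fixed terms are drawn from \code{level} (linear exaggeration), \code{level2}
#' (quadratic), \code{face_sex}, \code{rater_sex} and their interactions with
#' the level terms. Random structure lists the design terms given random
#' effects by participant and by face (always including \code{"intercept"}).
#'
#' @slot fixedTerms character vector of fixed-effect terms (intercept implicit).
#' @slot randomParticipant character vector of by-participant random terms.
#' @slot randomFace character vector of by-face random terms.
#' @slot label short model label used in WAIC ladders.
#'
#' @seealso [modelSpec()], [candidateModelSpecs()], [fitHierarchical()]
#' @export
setClass("ModelSpec",
  representation(fixedTerms = "character", randomParticipant = "character",
                 randomFace = "character", label = "character"))

.FIXED_TERMS <- c("level", "level2", "face_sex", "rater_sex",
                  "level:face_sex", "level2:face_sex",
                  "level:rater_sex", "level2:rater_sex")

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  ft <- object@fixedTerms
  if (!all(ft %in% .FIXED_TERMS))
    msg <- c(msg, paste("unknown fixed terms:",
                        paste(setdiff(ft, .FIXED_TERMS), collapse = ", ")))
  if (!"level" %in% ft)
    msg <- c(msg, "the linear level term is always required")
  if ("level2" %in% ft && !"level" %in% ft)
    msg <- c(msg, "quadratic term requires the linear term")
  for (t in grep(":", ft, value = TRUE)) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% ft))
      msg <- c(msg, sprintf("interaction '%s' requires its main effects", t))
  }
  if (!"intercept" %in% object@randomParticipant)
    msg <- c(msg, "by-participant random structure must include the intercept")
  if (length(msg)) msg else TRUE
})

#' PosteriorSummary: MCMC summaries of a fitted hierarchical model
#'
#' @slot summary data.frame with columns parameter, EAP, CrI_low, CrI_high,
#'   Rhat (central 95\% credible intervals; Rhat is NA for single-chain runs).
#' @slot draws numeric matrix (kept draws x monitored parameters).
#' @slot logLik numeric matrix (kept draws x observations) of pointwise
#'   log-likelihood, retained for WAIC; may have zero rows.
#' @slot mcmc list of sampler settings (iterations, burnIn, chains, seed, thin).
#' @slot spec the ModelSpec that was fitted (empty list for derived objects).
#' @slot data list with elements n (observations) and meta.
#'
#' @export
setClass("PosteriorSummary",
  representation(summary = "data.frame", draws = "matrix", logLik = "matrix",
                 mcmc = "list", spec = "list", data = "list"),
  prototype(logLik = matrix(numeric(0), 0, 0), mcmc = list(), spec = list(),
            data = list()))

setValidity("PosteriorSummary", function(object) {
  s <- object@summary
  need <- c("parameter", "EAP", "CrI_low", "CrI_high", "Rhat")
  if (!all(need %in% names(s)))
    return(paste("summary must have columns:", paste(need, collapse = ", ")))
  bad <- !is.na(s$EAP) & (s$CrI_low > s$EAP + 1e-12 | s$EAP > s$CrI_high + 1e-12)
  if (any(bad))
    return("CrI_low <= EAP <= CrI_high must hold for every parameter")
  TRUE
})

#' ModelComparison: WAIC ladder over candidate model specifications
#'
#' @slot ladder data.frame (model, WAIC, pWAIC) sorted by WAIC ascending.
#' @slot best label of the minimal-WAIC model.
#' @slot fits named list of PosteriorSummary objects for the candidates.
#' @slot failures named character vector of error messages for candidates that
#'   failed to fit.
#'
#' @export
setClass("ModelComparison",
  representation(ladder = "data.frame", best = "character", fits = "list",
                 failures = "character"),
  prototype(failures = character(0)))

setValidity("ModelComparison", function(object) {
  l <- object@ladder
  if (!all(c("model", "WAIC") %in% names(l)))
    return("ladder needs columns model, WAIC")
  if (nrow(l) && is.unsorted(l$WAIC))
    return("ladder must be sorted by WAIC ascending")
  if (nrow(l) && !identical(object@best, l$model[1]))
    return("best must be the head of the sorted ladder")
  TRUE
})

#' ReliabilityResult: inter-rater reliability statistic
#'
#' @slot statistic \code{"cronbach_alpha"} or \code{"icc2"}.
#' @slot estimate point estimate.
#' @slot F F statistic (ICC(2,1) only, else NA).
#' @slot df1,df2 F-test degrees of freedom (ICC(2,1) only).
#' @slot ciLow,ciHigh 95\% confidence bounds (ICC(2,1) only).
#' @slot nFaces,nRaters matrix dimensions the statistic was computed from.
#'
#' @export
setClass("ReliabilityResult",
  representation(statistic = "character", estimate = "numeric", F = "numeric",
                 df1 = "integer", df2 = "integer", ciLow = "numeric",
                 ciHigh = "numeric", nFaces = "integer", nRaters = "integer"),
  prototype(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
            ciLow = NA_real_, ciHigh = NA_real_))

setValidity("ReliabilityResult", function(object) {
  if (!object@statistic %in% c("cronbach_alpha", "icc2"))
    return("statistic must be 'cronbach_alpha' or 'icc2'")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !(object@ciLow <= object@estimate && object@estimate <= object@ciHigh))
    return("ciLow <= estimate <= ciHigh must hold")
  TRUE
})

#' CorrelationResult: posterior of a (rank) correlation coefficient
#'
#' @slot rhoEap posterior mean of rho.
#' @slot criLow,criHigh central 95\% credible interval.
#' @slot rhoDraws retained posterior draws of rho.
#' @slot deltaEap,deltaLow,deltaHigh posterior of a difference of two rhos
#'   (populated by [correlationDifference()], otherwise NA).
#' @slot deltaDraws retained draws of the difference.
#' @slot meta list: n, rank_transform flag, sampler settings.
#'
#' @export
setClass("CorrelationResult",
  representation(rhoEap = "numeric", criLow = "numeric", criHigh = "numeric",
                 rhoDraws = "numeric", deltaEap = "numeric",
                 deltaLow = "numeric", deltaHigh = "numeric",
                 deltaDraws = "numeric", meta = "list"),
  prototype(deltaEap = NA_real_, deltaLow = NA_real_, deltaHigh = NA_real_,
            deltaDraws = numeric(0), meta = list()))

setValidity("CorrelationResult", function(object) {
  if (!(object@criLow <= object@rhoEap && object@rhoEap <= object@criHigh))
    return("criLow <= rhoEap <= criHigh must hold")
  TRUE
})

#' GroundTruth: generator parameters with known trait directions
#'
#' The two true directions are unit vectors whose inner product (cosine) is
#' controlled, emulating the negative correlation between perceived
#' masculinity and attractiveness. Ratings arise from a latent linear +
#' quadratic percept with rater and face random effects, then an affine
#' Likert map with round-and-clip onto 1--9.
#'
#' @slot betaAttr,betaMasc true unit-norm 100-vectors.
#' @slot cosAngle their inner product.
#' @slot b0,b1,b2 latent intercept, linear gain, quadratic gain.
#' @slot sdRaterIntercept,sdRaterSlope,sdFace,sdResid noise SDs.
#' @slot likertCenter,likertGain affine latent-to-Likert map
#'   (rating = clip(round(center + gain * latent), 1, 9)).
#' @slot seed generator seed.
#'
#' @seealso [makeGroundTruth()], [simulateRatings()]
#' @export
setClass("GroundTruth",
  representation(betaAttr = "numeric", betaMasc = "numeric",
                 cosAngle = "numeric", b0 = "numeric", b1 = "numeric",
                 b2 = "numeric", sdRaterIntercept = "numeric",
                 sdRaterSlope = "numeric", sdFace = "numeric",
                 sdResid = "numeric", likertCenter = "numeric",
                 likertGain = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  for (nm in c("betaAttr", "betaMasc")) {
    v <- slot(object, nm)
    if (length(v) != .FACE_DIM) msg <- c(msg, sprintf("%s must be length 100", nm))
    else if (abs(sqrt(sum(v^2)) - 1) > 1e-10)
      msg <- c(msg, sprintf("%s must be unit norm", nm))
  }
  if (length(object@betaAttr) == .FACE_DIM && length(object@betaMasc) == .FACE_DIM &&
      abs(sum(object@betaAttr * object@betaMasc) - object@cosAngle) > 1e-8)
    msg <- c(msg, "achieved cosine must match cosAngle to 1e-8")
  if (any(c(object@sdRaterIntercept, object@sdRaterSlope, object@sdFace,
            object@sdResid) < 0))
    msg <- c(msg, "noise SDs must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SimConfig: scenario-level settings for the synthetic generator
#'
#' @slot scenario one of \code{exp1_model_building}, \code{exp1_validation},
#'   \code{exp2_attr_orth}, \code{exp2_sexdim_orth}.
#' @slot nFaces,nRaters design sizes.
#' @slot levels exaggeration levels in SD units.
#' @slot seed integer seed.
#'
#' @export
setClass("SimConfig",
  representation(scenario = "character", nFaces = "integer",
                 nRaters = "integer", levels = "numeric", seed = "integer"))

.SCENARIOS <- c("exp1_model_building", "exp1_validation",
                "exp2_attr_orth", "exp2_sexdim_orth")

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (!object@scenario %in% .SCENARIOS)
    msg <- c(msg, paste("scenario must be one of:",
                        paste(.SCENARIOS, collapse = ", ")))
  if (object@nFaces < 1 || object@nRaters < 1)
    msg <- c(msg, "nFaces and nRaters must be positive")
  if (length(msg)) msg else TRUE
})
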