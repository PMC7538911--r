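#' @include AllClasses.R faceSpace.R traitModel.R
NULL

#' Sample a synthetic face population
#'
#' Coordinates are iid standard normal in all 100 dimensions (the generator
#' population has the average face at the origin and unit SD per dimension);
#' sexes alternate male/female so any prefix is balanced.
#'
#' @param n number of faces.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return a [FaceSet-class]
#' @examples
#' fs <- sampleFaces(20, seed = 1)
#' @export
sampleFaces <- function(n, seed = 1) {
  stopifnot(n >= 1)
  coords <- withLocalSeed(seed, matrix(stats::rnorm(n * .FACE_DIM), n, .FACE_DIM))
  sex <- rep(c("male", "female"), length.out = n)
  FaceSet(coords, sex, faceIds = sprintf("face_%04d", seq_len(n)),
          provenance = sprintf("sampleFaces(n=%d, seed=%d)", n, seed))
}

#' Construct ground-truth trait directions with a controlled angle
#'
#' Draws one random unit vector for the attractiveness direction, then
#' rotates a second unit vector within a random 2-plane so the pair's inner
#' product equals \code{cosAngle} exactly. The default angles emulate the
#' observed negative rating correlations between masculinity and
#' attractiveness (around -0.4 for male faces, -0.7 for female faces).
#'
#' @param cosAngle cosine between the two true directions, in (-1, 1).
#' @param seed integer seed.
#' @param b0,b1,b2 latent intercept, linear gain and quadratic gain of the
#'   percept-to-rating curve.
#' @param sdRaterIntercept,sdRaterSlope,sdFace,sdResid noise SDs of the
#'   rater random intercept, rater random slope, face random effect and
#'   trial residual.
#' @param likertCenter,likertGain affine latent-to-Likert map; with the
#'   defaults a latent range of -3..+3 covers ratings about 2--8 before
#'   rounding and clipping to 1--9.
#' @return a [GroundTruth-class]
#' @export
makeGroundTruth <- function(cosAngle = -0.4, seed = 1, b0 = 0, b1 = 1,
                            b2 = -0.05, sdRaterIntercept = 0.5,
                            sdRaterSlope = 0.2, sdFace = 0.3, sdResid = 0.5,
                            likertCenter = 5, likertGain = 1) {
  if (abs(cosAngle) >= 1)
    stopf("|cosAngle| must be < 1, got %g", cosAngle)
  vecs <- withLocalSeed(seed, {
    v1 <- stats::rnorm(.FACE_DIM)
    v1 <- v1 / sqrt(sum(v1^2))
    v2 <- stats::rnorm(.FACE_DIM)
    v2 <- v2 - sum(v2 * v1) * v1
    v2 <- v2 / sqrt(sum(v2^2))
    list(attr = v1, masc = cosAngle * v1 + sqrt(1 - cosAngle^2) * v2)
  })
  new("GroundTruth", betaAttr = vecs$attr, betaMasc = vecs$masc,
      cosAngle = cosAngle, b0 = b0, b1 = b1, b2 = b2,
      sdRaterIntercept = sdRaterIntercept, sdRaterSlope = sdRaterSlope,
      sdFace = sdFace, sdResid = sdResid, likertCenter = likertCenter,
      likertGain = likertGain, seed = as.integer(seed))
}

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: cos(attr, masc) = %.3f, b1 = %g, b2 = %g\n",
              object@cosAngle, object@b1, object@b2))
  cat(sprintf("  noise SDs: rater intercept %g, rater slope %g, face %g, residual %g\n",
              object@sdRaterIntercept, object@sdRaterSlope, object@sdFace,
              object@sdResid))
})

# True latent percept of faces under one of the ground-truth directions.
.truePercept <- function(truth, faces, direction = c("attr", "masc")) {
  direction <- match.arg(direction)
  beta <- if (direction == "attr") truth@betaAttr else truth@betaMasc
  drop(faceCoords(faces) %*% beta)
}

# Map latent values onto the 1-9 Likert scale: affine, round, clip.
.likert <- function(truth, latent) {
  as.integer(pmin(9, pmax(1, round(truth@likertCenter +
                                     truth@likertGain * latent))))
}

#' Simulate Likert ratings of faces under a ground-truth direction
#'
#' Each rater p rates each face f through the latent model
#' \deqn{\ell_{pf} = b_0 + (b_1 + u^{(1)}_p) s_f + b_2 s_f^2 + u^{(0)}_p
#'   + w_f + \epsilon_{pf}}
#' where \eqn{s_f} is the face's true percept (its projection on the true
#' direction), \eqn{u} are rater random effects, \eqn{w_f} a face effect and
#' \eqn{\epsilon} trial noise; the latent value is then mapped onto the 1--9
#' Likert scale by an affine transform with rounding and clipping. Rater
#' sexes alternate male/female.
#'
#' @param faces a [FaceSet-class] of stimuli.
#' @param truth a [GroundTruth-class].
#' @param direction which true direction drives the percept:
#'   \code{"attr"} or \code{"masc"}.
#' @param nRaters number of raters.
#' @param seed integer seed.
#' @param levels optional per-face exaggeration level recorded in the trial
#'   table (default 0 for un-transformed faces).
#' @param transform optional transformation label recorded in the trial table.
#' @param participantOffset starting index for participant ids (so separate
#'   calls can produce disjoint participant pools).
#' @return list with elements \code{matrix} (a [RatingMatrix-class]) and
#'   \code{trials} (long-format data.frame)
#' @export
simulateRatings <- function(faces, truth, direction = c("attr", "masc"),
                            nRaters = 20, seed = 1, levels = NULL,
                            transform = NA_character_,
                            participantOffset = 0L) {
  direction <- match.arg(direction)
  stopifnot(is(faces, "FaceSet"), is(truth, "GroundTruth"), nRaters >= 1)
  s <- .truePercept(truth, faces, direction)
  n <- nFaces(faces)
  if (is.null(levels)) levels <- rep(0, n)
  stopifnot(length(levels) == n)
  lat <- withLocalSeed(seed, {
    u0 <- stats::rnorm(nRaters, 0, truth@sdRaterIntercept)
    u1 <- stats::rnorm(nRaters, 0, truth@sdRaterSlope)
    w <- stats::rnorm(n, 0, truth@sdFace)
    eps <- matrix(stats::rnorm(n * nRaters, 0, truth@sdResid), n, nRaters)
    base <- truth@b0 + truth@b1 * s + truth@b2 * s^2 + w
    outer(s, u1) + matrix(base, n, nRaters) +
      matrix(u0, n, nRaters, byrow = TRUE) + eps
  })
  vals <- matrix(.likert(truth, lat), n, nRaters)
  raterIds <- sprintf("p_%03d", participantOffset + seq_len(nRaters))
  raterSex <- rep(c("male", "female"), length.out = nRaters)
  task <- if (direction == "attr") "attractiveness" else "sexual_dimorphism"
  rownames(vals) <- faceIds(faces)
  colnames(vals) <- raterIds
  rm <- RatingMatrix(vals, faceSex = unname(faceSex(faces)),
                     raterSex = raterSex, task = task)
  trials <- data.frame(
    participant_id = rep(raterIds, each = n),
    rater_sex = rep(raterSex, each = n),
    face_id = rep(faceIds(faces), nRaters),
    face_sex = rep(unname(faceSex(faces)), nRaters),
    task = task,
    level_sd = rep(levels, nRaters),
    rating = as.integer(vals),
    stringsAsFactors = FALSE)
  if (!is.na(transform)) trials$transform <- transform
  list(matrix = rm, trials = trials)
}

#' Simulate the orthogonalized-transformation validation experiment
#'
#' Reproduces the second experiment's design in silico: 20 base faces are
#' exaggerated at seven levels (-3..+3 SD) along (i) the attractiveness
#' direction orthogonalized against sexual dimorphism and (ii) the sexual
#' dimorphism direction orthogonalized against attractiveness — 280 stimuli
#' in total — and separate participant groups rate each transformation on
#' each task (between-subjects, 4 cells). Percepts are computed from the
#' \emph{true} directions, so estimation error in the fitted directions
#' propagates realistically into nuisance-task ratings.
#'
#' @param truth a [GroundTruth-class].
#' @param attrDir,mascDir fitted, scaled [TraitDirection-class] objects for
#'   attractiveness and sexual dimorphism (not yet orthogonalized; the
#'   orthogonalized variants are computed here).
#' @param config a [SimConfig-class]; \code{nFaces} base faces,
#'   \code{nRaters} participants per cell, \code{levels} exaggeration levels.
#' @return list with \code{trials} (long data.frame over all four cells,
#'   with a \code{transform} column \code{"attr_orth"} /
#'   \code{"sexdim_orth"}), \code{stimuli} (named list of two
#'   [FaceSet-class]), and \code{directions} (the orthogonalized pair).
#' @export
simulateExperiment2 <- function(truth, attrDir, mascDir, config) {
  stopifnot(is(truth, "GroundTruth"), is(attrDir, "TraitDirection"),
            is(mascDir, "TraitDirection"), is(config, "SimConfig"))
  validObject(config)
  if (!attrDir@scaled || !mascDir@scaled)
    stopf("both directions must be scaled to SD units")
  attrOrth <- orthogonalize(attrDir, mascDir)
  mascOrth <- orthogonalize(mascDir, attrDir)
  base <- sampleFaces(config@nFaces, seed = childSeed(config@seed, "exp2base"))
  stimAttr <- transformFaces(base, attrOrth,
                             new("TransformSpec", directionName = "attr_orth",
                                 levels = config@levels))
  stimMasc <- transformFaces(base, mascOrth,
                             new("TransformSpec", directionName = "sexdim_orth",
                                 levels = config@levels))
  lvAttr <- parseTransformedIds(faceIds(stimAttr))$level
  lvMasc <- parseTransformedIds(faceIds(stimMasc))$level
  cells <- list(
    list(stim = stimAttr, lv = lvAttr, task = "attr", tf = "attr_orth"),
    list(stim = stimAttr, lv = lvAttr, task = "masc", tf = "attr_orth"),
    list(stim = stimMasc, lv = lvMasc, task = "attr", tf = "sexdim_orth"),
    list(stim = stimMasc, lv = lvMasc, task = "masc", tf = "sexdim_orth"))
  trials <- list()
  off <- 0L
  for (cell in cells) {
    sim <- simulateRatings(cell$stim, truth, direction = cell$task,
                           nRaters = config@nRaters,
                           seed = childSeed(config@seed,
                                            paste0(cell$task, cell$tf)),
                           levels = cell$lv, transform = cell$tf,
                           participantOffset = off)
    off <- off + config@nRaters
    trials[[length(trials) + 1]] <- sim$trials
  }
  list(trials = do.call(rbind, trials),
       stimuli = list(attr_orth = stimAttr, sexdim_orth = stimMasc),
       directions = list(attr_orth = attrOrth, sexdim_orth = mascOrth))
}

#' Construct a SimConfig
#'
#' Scenario defaults mirror the study designs: model building uses 400 faces
#' and 20 raters; the validation scenarios use 20 base faces, 7 levels
#' (-3..+3) and 16 raters per cell.
#'
#' @param scenario one of \code{"exp1_model_building"},
#'   \code{"exp1_validation"}, \code{"exp2_attr_orth"},
#'   \code{"exp2_sexdim_orth"}.
#' @param nFaces,nRaters,levels overrides of the scenario defaults.
#' @param seed integer seed.
#' @return a [SimConfig-class]
#' @export
simConfig <- function(scenario = "exp1_model_building", nFaces = NULL,
                      nRaters = NULL, levels = NULL, seed = 1) {
  defaults <- switch(scenario,
    exp1_model_building = list(nFaces = 400L, nRaters = 20L, levels = 0),
    exp1_validation = ,
    exp2_attr_orth = ,
    exp2_sexdim_orth = list(nFaces = 20L, nRaters = 16L, levels = -3:3),
    stopf("unknown scenario: %s", scenario))
  new("SimConfig", scenario = scenario,
      nFaces = as.integer(nFaces %||% defaults$nFaces),
      nRaters = as.integer(nRaters %||% defaults$nRaters),
      levels = as.numeric(levels %||% defaults$levels),
      seed = as.integer(seed))
}

#' Compare a fitted trait direction with the generator's ground truth
#'
#' @param truth a [GroundTruth-class].
#' @param fitted a [TraitDirection-class] (scaled or not; scaling is applied
#'   for the gain check).
#' @param direction which true direction to compare against.
#' @return list with \code{cosine} (cosine similarity of fitted beta and the
#'   true beta) and \code{scaleError} (relative error of the true-percept
#'   gain per exaggeration level, |beta_true . unitStep - 1|).
#' @export
recoveryReport <- function(truth, fitted, direction = c("attr", "masc")) {
  direction <- match.arg(direction)
  stopifnot(is(truth, "GroundTruth"), is(fitted, "TraitDirection"))
  bt <- if (direction == "attr") truth@betaAttr else truth@betaMasc
  bf <- fitted@beta
  nf <- sqrt(sum(bf^2))
  if (!length(bf) || nf == 0) stopf("degenerate fitted direction (zero beta)")
  cosine <- sum(bt * bf) / (sqrt(sum(bt^2)) * nf)
  if (!fitted@scaled) fitted <- scaleToSDUnits(fitted)
  scaleError <- abs(sum(bt * fitted@unitStep) - 1)
  list(cosine = cosine, scaleError = scaleError)
}
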