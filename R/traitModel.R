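#' @include AllClasses.R AllGenerics.R faceSpace.R
NULL

#' Construct a RatingMatrix
#'
#' @param values integer matrix faces x raters, entries on the 1--9 Likert
#'   scale; rownames face ids, colnames rater ids (generated if absent).
#' @param faceSex per-face sex labels.
#' @param raterSex per-rater sex labels.
#' @param task \code{"attractiveness"} or \code{"sexual_dimorphism"}.
#' @return a [RatingMatrix-class]
#' @export
RatingMatrix <- function(values, faceSex, raterSex,
                         task = c("attractiveness", "sexual_dimorphism")) {
  task <- match.arg(task)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("face_%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("rater_%02d", seq_len(ncol(values)))
  new("RatingMatrix", values = values, faceSex = as.character(faceSex),
      raterSex = as.character(raterSex), task = task)
}

#' @describeIn RatingMatrix number of faces (rows)
#' @param x a RatingMatrix
#' @export
setMethod("nFaces", "RatingMatrix", function(x) nrow(x@values))

#' @describeIn RatingMatrix face ids
#' @export
setMethod("faceIds", "RatingMatrix", function(x) rownames(x@values))

#' @describeIn RatingMatrix face sex labels
#' @export
setMethod("faceSex", "RatingMatrix",
          function(x) stats::setNames(x@faceSex, faceIds(x)))

#' @export
setMethod("show", "RatingMatrix", function(object) {
  cat(sprintf("RatingMatrix: %d faces x %d raters, task = %s\n",
              nrow(object@values), ncol(object@values), object@task))
})

#' Ratings of a RatingMatrix as an integer matrix
#' @param x a RatingMatrix
#' @return integer matrix faces x raters
#' @export
ratingValues <- function(x) {
  stopifnot(is(x, "RatingMatrix"))
  x@values
}

#' Standardize mean ratings across faces
#'
#' Averages ratings over raters per face, then z-scores the per-face means
#' across faces using the sample SD (n-1 denominator), mirroring the
#' model-building step where mean rating scores are standardized before the
#' linear fit.
#'
#' @param ratings a [RatingMatrix-class]
#' @return a [StandardizedScores-class] with mean 0 and sample SD 1
#' @examples
#' rm <- RatingMatrix(matrix(c(2L, 5L, 8L, 2L, 5L, 8L), 3, 2),
#'                    faceSex = c("male", "male", "female"),
#'                    raterSex = c("male", "female"))
#' standardizeScores(rm)
#' @export
standardizeScores <- function(ratings) {
  stopifnot(is(ratings, "RatingMatrix"))
  validObject(ratings)
  m <- rowMeans(ratings@values)
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0)
    stopf("degenerate ratings: per-face means have zero variance across faces")
  z <- (m - mean(m)) / s
  new("StandardizedScores", score = z, task = ratings@task,
      nRaters = ncol(ratings@values), faceSex = ratings@faceSex)
}

#' @describeIn standardizeScores face ids of the scores
#' @param x a StandardizedScores
#' @export
setMethod("faceIds", "StandardizedScores", function(x) names(x@score))

#' @export
setMethod("show", "StandardizedScores", function(object) {
  cat(sprintf("StandardizedScores: %d faces, task = %s, %d raters\n",
              length(object@score), object@task, object@nRaters))
})

#' Scores of a StandardizedScores object
#' @param x a StandardizedScores
#' @return named numeric vector of z-scores
#' @export
scoreValues <- function(x) {
  stopifnot(is(x, "StandardizedScores"))
  x@score
}

#' Fit a trait direction as the best linear fit of scores onto coordinates
#'
#' Ordinary least squares of the standardized per-face scores on the 100 face
#' coordinates: score ~ intercept + beta . coords. Requires more faces than
#' dimensions (n > 100). With \code{sexPolicy = "per_face_sex"} the fit is
#' done separately within male and female faces and a named list of two
#' directions is returned.
#'
#' @param faces a [FaceSet-class]
#' @param scores a [StandardizedScores-class]; face ids must match the faces.
#' @param sexPolicy \code{"pooled"} (one joint fit, the default) or
#'   \code{"per_face_sex"}.
#' @param name direction name recorded on the result (defaults to the task).
#' @return a [TraitDirection-class], or a named list of two when fitting per
#'   face sex. The returned direction is unscaled; see [scaleToSDUnits()].
#' @export
fitTraitDirection <- function(faces, scores,
                              sexPolicy = c("pooled", "per_face_sex"),
                              name = NULL) {
  sexPolicy <- match.arg(sexPolicy)
  stopifnot(is(faces, "FaceSet"), is(scores, "StandardizedScores"))
  if (is.null(name)) name <- scores@task
  ids <- faceIds(scores)
  if (!setequal(ids, faceIds(faces)) || length(ids) != nFaces(faces))
    stopf("face ids of scores and faces do not match")
  X <- faceCoords(faces)[ids, , drop = FALSE]
  y <- scoreValues(scores)
  fit1 <- function(Xs, ys, tag) {
    if (nrow(Xs) <= .FACE_DIM)
      stopf("underdetermined fit: need more than %d faces, have %d (%s)",
            .FACE_DIM, nrow(Xs), tag)
    co <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), ys)$coefficients
    new("TraitDirection", name = name, beta = unname(co[-1]),
        intercept = unname(co[1]), unitStep = numeric(0), scaled = FALSE,
        fittedOn = list(n_faces = nrow(Xs), task = scores@task,
                        sex_policy = sexPolicy, subset = tag),
        orthogonalizedAgainst = NA_character_)
  }
  if (sexPolicy == "pooled") return(fit1(X, y, "all"))
  sx <- scores@faceSex
  out <- lapply(c(male = "male", female = "female"), function(s)
    fit1(X[sx == s, , drop = FALSE], y[sx == s], s))
  out
}

#' Rescale a trait direction so one level equals one score SD
#'
#' Sets \code{unitStep = beta / (beta . beta)}, the displacement along beta
#' that raises the predicted standardized score by exactly 1. This defines
#' the "SD unit" of exaggeration: moving a face by \code{k * unitStep}
#' changes its predicted score by \code{k}.
#'
#' @param direction a fitted [TraitDirection-class]
#' @return the direction with \code{unitStep} set and \code{scaled = TRUE}
#' @export
scaleToSDUnits <- function(direction) {
  stopifnot(is(direction, "TraitDirection"))
  b <- direction@beta
  ss <- sum(b^2)
  if (!length(b) || ss == 0)
    stopf("degenerate direction: beta is zero, cannot scale")
  direction@unitStep <- b / ss
  direction@scaled <- TRUE
  validObject(direction)
  direction
}

#' Orthogonalize a target trait direction against a nuisance direction
#'
#' Gram-Schmidt projection in the Euclidean metric of the coordinate space:
#' the component of the target's beta along the nuisance's beta is removed,
#' \deqn{b_\perp = b_t - \frac{b_t \cdot b_n}{b_n \cdot b_n} b_n,}
#' and the result is rescaled with [scaleToSDUnits()]. Moving any face along
#' the returned direction's \code{unitStep} then leaves the nuisance
#' direction's predicted score unchanged (to machine precision) while still
#' changing the target's predicted score by one per level.
#'
#' @param target the [TraitDirection-class] to purge.
#' @param nuisance the direction whose contribution is removed.
#' @return the orthogonalized, rescaled target direction, with
#'   \code{orthogonalizedAgainst} recorded.
#' @export
orthogonalize <- function(target, nuisance) {
  stopifnot(is(target, "TraitDirection"), is(nuisance, "TraitDirection"))
  bt <- target@beta
  bn <- nuisance@beta
  if (!length(bt) || !length(bn))
    stopf("both directions must be fitted before orthogonalization")
  bperp <- bt - (sum(bt * bn) / sum(bn * bn)) * bn
  if (sqrt(sum(bperp^2)) / sqrt(sum(bt^2)) < 1e-12)
    stopf("degenerate orthogonalization: '%s' is parallel to '%s'",
          target@name, nuisance@name)
  target@beta <- bperp
  target <- scaleToSDUnits(target)
  target@orthogonalizedAgainst <- nuisance@name
  target
}

#' @describeIn predictScore scores for every face in a FaceSet
#' @export
setMethod("predictScore", signature("TraitDirection", "FaceSet"),
  function(direction, faces) {
    drop(faceCoords(faces) %*% direction@beta) + direction@intercept
  })

#' @describeIn predictScore score of a bare coordinate vector
#' @export
setMethod("predictScore", signature("TraitDirection", "numeric"),
  function(direction, faces) {
    stopifnot(length(faces) == .FACE_DIM)
    sum(direction@beta * faces) + direction@intercept
  })

#' @describeIn TraitDirection fitted coefficients
#' @param x a TraitDirection
#' @export
setMethod("directionBeta", "TraitDirection", function(x) x@beta)

#' @describeIn TraitDirection per-level displacement (errors if unscaled)
#' @export
setMethod("unitStep", "TraitDirection", function(x) {
  if (!x@scaled) stopf("direction '%s' has not been scaled to SD units", x@name)
  x@unitStep
})

#' @export
setMethod("show", "TraitDirection", function(object) {
  cat(sprintf("TraitDirection '%s'%s%s\n", object@name,
              if (object@scaled) " [scaled]" else " [unscaled]",
              if (!is.na(object@orthogonalizedAgainst))
                sprintf(" orthogonal to '%s'", object@orthogonalizedAgainst)
              else ""))
  if (length(object@beta))
    cat(sprintf("  |beta| = %.4f, intercept = %.4f\n",
                sqrt(sum(object@beta^2)), object@intercept))
  if (length(object@fittedOn))
    cat(sprintf("  fitted on %s faces (%s, %s)\n",
                object@fittedOn$n_faces %||% "?",
                object@fittedOn$task %||% "?",
                object@fittedOn$sex_policy %||% "?"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a TraitDirection to a JSON artifact
#'
#' @param direction a [TraitDirection-class]
#' @param path output file
#' @return invisibly, the path
#' @seealso [readTraitDirection()]
#' @export
writeTraitDirection <- function(direction, path) {
  stopifnot(is(direction, "TraitDirection"))
  obj <- list(name = direction@name, beta = direction@beta,
              intercept = direction@intercept, unit_step = direction@unitStep,
              scaled = direction@scaled,
              orthogonalized_against = direction@orthogonalizedAgainst,
              fitted_on = direction@fittedOn)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a TraitDirection from a JSON artifact
#'
#' @param path file written by [writeTraitDirection()]
#' @return a [TraitDirection-class]
#' @export
readTraitDirection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("TraitDirection", name = obj$name, beta = as.numeric(obj$beta),
      intercept = as.numeric(obj$intercept),
      unitStep = as.numeric(obj$unit_step %||% numeric(0)),
      scaled = isTRUE(obj$scaled),
      fittedOn = as.list(obj$fitted_on %||% list()),
      orthogonalizedAgainst = as.character(obj$orthogonalized_against %||%
                                             NA_character_))
}

#' Read a long-format rating/trial table
#'
#' Comma-delimited with header
#' \code{participant_id,rater_sex,face_id,face_sex,task,level_sd,rating}
#' (an optional \code{transform} column is preserved).
#'
#' @param path file to read
#' @return a data.frame of trials (one row per rating event)
#' @export
readTrials <- function(path) {
  if (!file.exists(path)) stopf("trials file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "rater_sex", "face_id", "face_sex", "task",
            "level_sd", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("trials file missing columns: %s", paste(miss, collapse = ", "))
  validateTrials(df)
  df
}

#' Write a long-format trial table
#'
#' @param trials data.frame of trials
#' @param path output file
#' @return invisibly, the path
#' @export
writeTrials <- function(trials, path) {
  validateTrials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared trial-table checks (1-9 integer ratings, known sexes/tasks).
validateTrials <- function(df) {
  if (any(df$rating < 1 | df$rating > 9 | df$rating != round(df$rating)))
    stopf("ratings must be integers in [1, 9]")
  if (!all(df$face_sex %in% .FACE_SEXES))
    stopf("face_sex must be 'male' or 'female'")
  if (!all(df$rater_sex %in% .FACE_SEXES))
    stopf("rater_sex must be 'male' or 'female'")
  if (!all(df$task %in% .TASKS))
    stopf("task must be one of: %s", paste(.TASKS, collapse = ", "))
  if (any(!is.finite(df$level_sd)))
    stopf("level_sd must be finite")
  invisible(df)
}

#' Pivot a long trial table into a RatingMatrix
#'
#' @param trials data.frame with the long-format trial columns; must contain
#'   one rating per (face, participant) pair after any subsetting.
#' @return a [RatingMatrix-class]
#' @export
trialsToRatingMatrix <- function(trials) {
  validateTrials(trials)
  task <- unique(trials$task)
  if (length(task) != 1)
    stopf("trials must contain a single task, found: %s",
          paste(task, collapse = ", "))
  wide <- stats::xtabs(rating ~ face_id + participant_id, data = trials)
  cnt <- stats::xtabs(~ face_id + participant_id, data = trials)
  if (any(cnt != 1))
    stopf("expected exactly one rating per (face, participant) pair")
  m <- matrix(as.integer(wide), nrow(wide), ncol(wide),
              dimnames = list(rownames(wide), colnames(wide)))
  fsex <- trials$face_sex[match(rownames(m), trials$face_id)]
  rsex <- trials$rater_sex[match(colnames(m), trials$participant_id)]
  RatingMatrix(m, faceSex = fsex, raterSex = rsex, task = task)
}
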