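#' @include AllClasses.R
NULL

#' Number of faces in a FaceSet or RatingMatrix
#' @param x a FaceSet or RatingMatrix
#' @return integer count
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Face identifiers
#' @param x a FaceSet, RatingMatrix or StandardizedScores
#' @return character vector of face ids
#' @export
setGeneric("faceIds", function(x) standardGeneric("faceIds"))

#' Face sex labels
#' @param x a FaceSet, RatingMatrix or StandardizedScores
#' @return character vector, \code{"male"}/\code{"female"} per face
#' @export
setGeneric("faceSex", function(x) standardGeneric("faceSex"))

#' Coordinate matrix of a FaceSet
#' @param x a FaceSet
#' @return numeric matrix, faces x 100, rownames = face ids
#' @export
setGeneric("faceCoords", function(x) standardGeneric("faceCoords"))

#' Fitted coefficients of a TraitDirection
#' @param x a TraitDirection
#' @return numeric(100)
#' @export
setGeneric("directionBeta", function(x) standardGeneric("directionBeta"))

#' Per-level coordinate displacement of a scaled TraitDirection
#' @param x a scaled TraitDirection
#' @return numeric(100)
#' @export
setGeneric("unitStep", function(x) standardGeneric("unitStep"))

#' Predicted trait score of faces under a fitted direction
#'
#' Computes intercept + beta . coords for each face.
#'
#' @param direction a fitted TraitDirection
#' @param faces a FaceSet or a numeric vector of 100 coordinates
#' @return named numeric vector of predicted standardized scores
#' @export
setGeneric("predictScore",
           function(direction, faces) standardGeneric("predictScore"))

#' Distance of faces from a reference face (averageness)
#'
#' Euclidean distance in the 100-dimensional coordinate space; the origin is
#' the average face of the generator population, so the default measures how
#' far a face sits from the population average. Along any transform ray the
#' distance is a convex (U-shaped) function of the exaggeration level.
#'
#' @param face a FaceSet or numeric(100)
#' @param reference a numeric(100) reference point (default: origin)
#' @return non-negative numeric, one value per face
#' @export
setGeneric("averageness",
           function(face, reference = numeric(100)) standardGeneric("averageness"))

#' Posterior summary table
#' @param x a PosteriorSummary
#' @return data.frame with parameter, EAP, CrI_low, CrI_high, Rhat
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

#' Retained posterior draws
#' @param x a PosteriorSummary or CorrelationResult
#' @return matrix (draws x parameters) or numeric vector of rho draws
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
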