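#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FaceSet from a coordinate matrix
#'
#' @param coords numeric matrix, faces x 100; rownames used as face ids (or
#'   supply \code{faceIds}).
#' @param faceSex character vector of \code{"male"}/\code{"female"}, one per face.
#' @param faceIds optional character vector of ids; overrides rownames.
#' @param provenance free-text provenance string.
#' @return a [FaceSet-class]
#' @examples
#' fs <- FaceSet(matrix(rnorm(300), 3, 100), rep(c("male", "female"), c(2, 1)))
#' nFaces(fs)
#' @export
FaceSet <- function(coords, faceSex, faceIds = NULL, provenance = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!is.null(faceIds)) rownames(coords) <- faceIds
  if (is.null(rownames(coords)) && nrow(coords) > 0)
    rownames(coords) <- sprintf("face_%03d", seq_len(nrow(coords)))
  colnames(coords) <- sprintf("dim_%03d", seq_len(ncol(coords)))
  new("FaceSet", coords = coords, faceSex = as.character(faceSex),
      provenance = provenance)
}

#' @describeIn FaceSet number of faces
#' @param x a FaceSet
#' @export
setMethod("nFaces", "FaceSet", function(x) nrow(x@coords))

#' @describeIn FaceSet face identifiers
#' @export
setMethod("faceIds", "FaceSet", function(x) rownames(x@coords))

#' @describeIn FaceSet face sex labels
#' @export
setMethod("faceSex", "FaceSet", function(x) stats::setNames(x@faceSex, faceIds(x)))

#' @describeIn FaceSet coordinate matrix (faces x 100)
#' @export
setMethod("faceCoords", "FaceSet", function(x) x@coords)

#' @export
setMethod("show", "FaceSet", function(object) {
  cat(sprintf("FaceSet with %d faces x %d dimensions\n",
              nrow(object@coords), ncol(object@coords)))
  if (nrow(object@coords)) {
    tab <- table(factor(object@faceSex, levels = .FACE_SEXES))
    cat(sprintf("  sex: %d male, %d female\n", tab[["male"]], tab[["female"]]))
  }
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' @describeIn FaceSet subset faces by index or id
#' @param i index, logical or character vector of face ids
#' @param j,drop,... ignored
#' @export
setMethod("[", "FaceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, faceIds(x))
  idx <- seq_len(nFaces(x))[i]
  new("FaceSet", coords = x@coords[idx, , drop = FALSE],
      faceSex = x@faceSex[idx], provenance = x@provenance)
})

#' Read faces from a delimited-text coordinate table
#'
#' Expects a comma-delimited file with header
#' \code{face_id,face_sex,dim_001,...,dim_100}: one row per face, 100
#' coordinate columns.
#'
#' @param path file to read.
#' @return a [FaceSet-class] preserving the file's row order.
#' @seealso [writeFaces()]
#' @export
readFaces <- function(path) {
  if (!file.exists(path)) stopf("faces file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("face_id", "face_sex") %in% names(df)))
    stopf("faces file must have 'face_id' and 'face_sex' columns")
  dimCols <- setdiff(names(df), c("face_id", "face_sex"))
  if (length(dimCols) != .FACE_DIM)
    stopf("faces file must have %d coordinate columns, found %d",
          .FACE_DIM, length(dimCols))
  coords <- matrix(NA_real_, nrow(df), .FACE_DIM)
  for (k in seq_along(dimCols)) {
    v <- suppressWarnings(as.numeric(df[[dimCols[k]]]))
    bad <- which(is.na(v) & !is.na(df[[dimCols[k]]]) | !is.finite(v))
    if (length(bad))
      stopf("non-numeric coordinate in column '%s', row for face '%s'",
            dimCols[k], df$face_id[bad[1]])
    coords[, k] <- v
  }
  FaceSet(coords, df$face_sex, faceIds = df$face_id,
          provenance = paste("read from", path))
}

#' Write a FaceSet to a delimited-text coordinate table
#'
#' Coordinates are serialized with 17 significant digits so that
#' \code{readFaces(writeFaces(S))} reproduces ids, sexes and coordinates
#' exactly; output is byte-stable for a fixed input.
#'
#' @param faces a [FaceSet-class]
#' @param path output file
#' @return invisibly, the path written
#' @export
writeFaces <- function(faces, path) {
  stopifnot(is(faces, "FaceSet"))
  validObject(faces)
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- paste(c("face_id", "face_sex", sprintf("dim_%03d", 1:.FACE_DIM)),
                  collapse = ",")
  writeLines(header, con)
  if (nFaces(faces) > 0) {
    num <- apply(faces@coords, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ","))
    writeLines(paste(faceIds(faces), faces@faceSex, num, sep = ","), con)
  }
  invisible(path)
}

#' Construct a TransformSpec
#'
#' @param directionName name of the direction to apply.
#' @param levels exaggeration levels in SD units, sorted ascending;
#'   default \code{-3:3} (seven levels, as in the validation design).
#' @return a [TransformSpec-class]
#' @export
TransformSpec <- function(directionName, levels = -3:3) {
  new("TransformSpec", directionName = directionName,
      levels = as.numeric(levels))
}

#' Exaggerate faces along a scaled trait direction
#'
#' Each input face is displaced by \code{level * unitStep(direction)} for
#' every level in \code{spec}, producing \code{nFaces * length(levels)}
#' output faces. One unit of level corresponds to one SD of the direction's
#' predicted standardized score. Output ids encode the source face, the
#' direction name and the level as \code{"{source}:{direction}:{level:+.1f}"}.
#'
#' @param faces a [FaceSet-class]
#' @param direction a scaled [TraitDirection-class] (see [scaleToSDUnits()])
#' @param spec a [TransformSpec-class]
#' @return a [FaceSet-class] of transformed faces
#' @examples
#' \dontrun{
#' exag <- transformFaces(fs, dir, TransformSpec("attractiveness", -3:3))
#' }
#' @export
transformFaces <- function(faces, direction, spec) {
  stopifnot(is(faces, "FaceSet"), is(direction, "TraitDirection"),
            is(spec, "TransformSpec"))
  validObject(spec)
  if (!direction@scaled)
    stopf("direction '%s' must be scaled to SD units before transforming (see scaleToSDUnits)",
          direction@name)
  lv <- spec@levels
  n <- nFaces(faces)
  out <- matrix(NA_real_, n * length(lv), .FACE_DIM)
  ids <- character(n * length(lv))
  sex <- character(n * length(lv))
  step <- direction@unitStep
  for (j in seq_along(lv)) {
    rows <- (j - 1L) * n + seq_len(n)
    out[rows, ] <- faces@coords + matrix(lv[j] * step, n, .FACE_DIM, byrow = TRUE)
    ids[rows] <- sprintf("%s:%s:%+.1f", faceIds(faces), spec@directionName, lv[j])
    sex[rows] <- faces@faceSex
  }
  FaceSet(out, sex, faceIds = ids,
          provenance = sprintf("transform of %d faces along '%s' at %d levels",
                               n, spec@directionName, length(lv)))
}

#' Parse transformed-face ids back into source id, direction and level
#'
#' @param ids character vector of ids produced by [transformFaces()]
#' @return data.frame with columns source, direction, level
#' @export
parseTransformedIds <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stopf("id '%s' is not a transformed-face id", ids[bad][1])
  data.frame(
    source = vapply(parts, function(p) paste(p[seq_len(length(p) - 2)],
                                             collapse = ":"), ""),
    direction = vapply(parts, function(p) p[length(p) - 1], ""),
    level = as.numeric(vapply(parts, function(p) p[length(p)], "")),
    stringsAsFactors = FALSE)
}

#' @describeIn averageness distance of each face in a FaceSet from the reference
#' @export
setMethod("averageness", "FaceSet", function(face, reference = numeric(100)) {
  stopifnot(length(reference) == .FACE_DIM)
  d <- sweep(face@coords, 2, reference)
  stats::setNames(sqrt(rowSums(d^2)), faceIds(face))
})

#' @describeIn averageness distance of a bare coordinate vector
#' @export
setMethod("averageness", "numeric", function(face, reference = numeric(100)) {
  stopifnot(length(face) == .FACE_DIM, length(reference) == .FACE_DIM)
  sqrt(sum((face - reference)^2))
})
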