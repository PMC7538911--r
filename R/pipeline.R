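#' @include AllClasses.R faceSpace.R traitModel.R hierModel.R syntheticData.R
NULL

# Canonical JSON + md5 of a config list, for manifest traceability.
.configHash <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.writeManifest <- function(command, config, artifacts, outDir) {
  manifest <- list(command = command, config = config,
                   config_hash = .configHash(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("facespace")),
                   artifacts = artifacts)
  path <- file.path(outDir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.msg <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run one stage of the face-space modelling pipeline
#'
#' Orchestrates the package's functions as a set of file-to-file commands so
#' a full study can be reproduced from a configuration list (or YAML file).
#' Every stage writes a manifest recording the configuration, its hash, the
#' seed and the package version; deterministic stages are bit-reproducible
#' from the manifest.
#'
#' Commands and their artifacts:
#' \describe{
#'   \item{simulate}{synthetic faces + rating tables; with
#'     \code{scenario = "exp2"} it instead simulates the validation
#'     experiment from saved direction artifacts and ground truth.}
#'   \item{build}{fit + scale both trait directions from faces and ratings,
#'     saved as JSON artifacts.}
#'   \item{orthogonalize}{orthogonalized direction pair.}
#'   \item{transform}{transformed face file along a saved direction.}
#'   \item{validate}{hierarchical-model posterior summaries (and with
#'     \code{model_selection: true} a WAIC ladder) per transformation x task
#'     cell of an exp2-style trial table.}
#'   \item{compare}{generated-quantity contrast table from two saved draw
#'     tables.}
#'   \item{report}{dissociation checks; prints and writes PASS/FAIL lines.}
#' }
#'
#' @param command one of \code{simulate}, \code{build}, \code{orthogonalize},
#'   \code{transform}, \code{validate}, \code{compare}, \code{report}.
#' @param config named list of parameters, or the path of a YAML file
#'   containing one. Common fields: \code{out_dir} (required), \code{seed};
#'   see the command descriptions for the rest.
#' @param verbose print progress messages (default TRUE).
#' @return invisibly, a named list of artifact paths (including the
#'   manifest).
#' @export
runPipeline <- function(command, config, verbose = TRUE) {
  commands <- c("simulate", "build", "orthogonalize", "transform",
                "validate", "compare", "report")
  if (!command %in% commands)
    stopf("unknown command '%s'; expected one of: %s", command,
          paste(commands, collapse = ", "))
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stopf("config must set out_dir")
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  arts <- switch(command,
    simulate = .cmdSimulate(config, outDir, verbose),
    build = .cmdBuild(config, outDir, verbose),
    orthogonalize = .cmdOrthogonalize(config, outDir, verbose),
    transform = .cmdTransform(config, outDir, verbose),
    validate = .cmdValidate(config, outDir, verbose),
    compare = .cmdCompare(config, outDir, verbose),
    report = .cmdReport(config, outDir, verbose))
  arts$manifest <- .writeManifest(command, config, arts, outDir)
  invisible(arts)
}

.readTruthJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GroundTruth", betaAttr = o$beta_attr, betaMasc = o$beta_masc,
      cosAngle = o$cos_angle, b0 = o$b0, b1 = o$b1, b2 = o$b2,
      sdRaterIntercept = o$sd_rater_intercept, sdRaterSlope = o$sd_rater_slope,
      sdFace = o$sd_face, sdResid = o$sd_resid,
      likertCenter = o$likert_center, likertGain = o$likert_gain,
      seed = as.integer(o$seed))
}

.writeTruthJson <- function(truth, path) {
  jsonlite::write_json(list(
    beta_attr = truth@betaAttr, beta_masc = truth@betaMasc,
    cos_angle = truth@cosAngle, b0 = truth@b0, b1 = truth@b1, b2 = truth@b2,
    sd_rater_intercept = truth@sdRaterIntercept,
    sd_rater_slope = truth@sdRaterSlope, sd_face = truth@sdFace,
    sd_resid = truth@sdResid, likert_center = truth@likertCenter,
    likert_gain = truth@likertGain, seed = truth@seed),
    path, auto_unbox = TRUE, digits = NA)
  path
}

.cmdSimulate <- function(config, outDir, verbose) {
  scenario <- config$scenario %||% "exp1_model_building"
  truth <- makeGroundTruth(cosAngle = config$cos_angle %||% -0.4,
                           seed = childSeed(config$seed, "truth"))
  if (scenario == "exp2") {
    attrDir <- readTraitDirection(config$attr_direction)
    mascDir <- readTraitDirection(config$masc_direction)
    truth <- .readTruthJson(config$ground_truth)
    sc <- simConfig("exp2_attr_orth", nFaces = config$n_faces %||% 20,
                    nRaters = config$n_raters %||% 16, seed = config$seed)
    sim <- simulateExperiment2(truth, attrDir, mascDir, sc)
    trialsPath <- file.path(outDir, "trials_exp2.csv")
    writeTrials(sim$trials, trialsPath)
    .msg(verbose, "simulate[exp2]: %d trials -> %s", nrow(sim$trials), trialsPath)
    return(list(trials = trialsPath))
  }
  n <- as.integer(config$n_faces %||% 400)
  k <- as.integer(config$n_raters %||% 20)
  faces <- sampleFaces(n, seed = childSeed(config$seed, "faces"))
  facesPath <- file.path(outDir, "faces.csv")
  writeFaces(faces, facesPath)
  truthPath <- .writeTruthJson(truth, file.path(outDir, "ground_truth.json"))
  arts <- list(faces = facesPath, ground_truth = truthPath)
  for (d in c("attr", "masc")) {
    sim <- simulateRatings(faces, truth, direction = d, nRaters = k,
                           seed = childSeed(config$seed, paste0("rate_", d)))
    p <- file.path(outDir, sprintf("trials_%s.csv", d))
    writeTrials(sim$trials, p)
    arts[[paste0("trials_", d)]] <- p
  }
  .msg(verbose, "simulate: %d faces x %d raters (seed %d) -> %s",
       n, k, config$seed, outDir)
  arts
}

.cmdBuild <- function(config, outDir, verbose) {
  faces <- readFaces(config$faces %||% file.path(outDir, "faces.csv"))
  arts <- list()
  for (d in c("attr", "masc")) {
    trials <- readTrials(config[[paste0("trials_", d)]] %||%
                           file.path(outDir, sprintf("trials_%s.csv", d)))
    scores <- standardizeScores(trialsToRatingMatrix(trials))
    dir <- scaleToSDUnits(fitTraitDirection(faces, scores,
                                            sexPolicy = config$sex_policy %||% "pooled"))
    p <- file.path(outDir, sprintf("direction_%s.json", d))
    writeTraitDirection(dir, p)
    arts[[paste0("direction_", d)]] <- p
    .msg(verbose, "build: fitted '%s' on %d faces -> %s", dir@name,
         nFaces(faces), p)
  }
  arts
}

.cmdOrthogonalize <- function(config, outDir, verbose) {
  attrDir <- readTraitDirection(config$attr_direction %||%
                                  file.path(outDir, "direction_attr.json"))
  mascDir <- readTraitDirection(config$masc_direction %||%
                                  file.path(outDir, "direction_masc.json"))
  aPath <- file.path(outDir, "direction_attr_orth.json")
  mPath <- file.path(outDir, "direction_sexdim_orth.json")
  writeTraitDirection(orthogonalize(attrDir, mascDir), aPath)
  writeTraitDirection(orthogonalize(mascDir, attrDir), mPath)
  .msg(verbose, "orthogonalize: wrote %s, %s", aPath, mPath)
  list(attr_orth = aPath, sexdim_orth = mPath)
}

.cmdTransform <- function(config, outDir, verbose) {
  faces <- readFaces(config$faces)
  dir <- readTraitDirection(config$direction)
  levels <- as.numeric(config$levels %||% (-3:3))
  out <- transformFaces(faces, dir, TransformSpec(dir@name, levels))
  p <- file.path(outDir, config$output %||% "faces_transformed.csv")
  writeFaces(out, p)
  .msg(verbose, "transform: %d faces x %d levels -> %s", nFaces(faces),
       length(levels), p)
  list(faces_transformed = p)
}

.cmdValidate <- function(config, outDir, verbose) {
  trials <- readTrials(config$trials %||% file.path(outDir, "trials_exp2.csv"))
  if (is.null(trials$transform)) trials$transform <- "all"
  mc <- config$mcmc %||% list()
  mcmc <- mcmcControl(iterations = mc$iterations %||% 2000,
                      burnIn = mc$burn_in %||% 500,
                      chains = mc$chains %||% 2,
                      seed = childSeed(config$seed, "validate"))
  spec <- modelSpec(c("level", "level2", "face_sex", "level:face_sex",
                      "level2:face_sex"))
  arts <- list()
  for (tf in unique(trials$transform)) for (task in unique(trials$task)) {
    cell <- trials[trials$transform == tf & trials$task == task, ]
    if (!nrow(cell)) next
    tag <- sprintf("%s_%s", tf, task)
    if (isTRUE(config$model_selection)) {
      cmp <- selectBest(cell, candidateModelSpecs(), mcmc)
      lp <- file.path(outDir, sprintf("waic_%s.csv", tag))
      writeSummaryTable(cmp, lp)
      arts[[paste0("waic_", tag)]] <- lp
      fit <- bestFit(cmp)
      .msg(verbose, "validate[%s]: best model '%s'", tag, cmp@best)
    } else {
      fit <- fitHierarchical(cell, spec, mcmc)
    }
    sp <- file.path(outDir, sprintf("posterior_%s.csv", tag))
    writeSummaryTable(fit, sp)
    dp <- file.path(outDir, sprintf("draws_%s.csv", tag))
    utils::write.csv(as.data.frame(fit@draws), dp, row.names = FALSE)
    arts[[paste0("posterior_", tag)]] <- sp
    arts[[paste0("draws_", tag)]] <- dp
    bad <- fit@summary$Rhat > 1.01
    if (any(bad, na.rm = TRUE))
      .msg(verbose, "validate[%s]: WARNING Rhat > 1.01 for %s", tag,
           paste(fit@summary$parameter[which(bad)], collapse = ", "))
    .msg(verbose, "validate[%s]: %d trials -> %s", tag, nrow(cell), sp)
  }
  arts
}

.cmdCompare <- function(config, outDir, verbose) {
  term <- config$term %||% "level"
  mkFit <- function(path) {
    d <- as.matrix(utils::read.csv(path, check.names = FALSE))
    q <- apply(d, 2, stats::quantile, probs = c(0.025, 0.975))
    new("PosteriorSummary",
        summary = data.frame(parameter = colnames(d), EAP = colMeans(d),
                             CrI_low = q[1, ], CrI_high = q[2, ],
                             Rhat = NA_real_),
        draws = d, logLik = matrix(numeric(0), 0, 0), mcmc = list(),
        spec = list(), data = list(n = nrow(d)))
  }
  gq <- generatedQuantities(mkFit(config$draws_a), mkFit(config$draws_b), term)
  p <- file.path(outDir, config$output %||% "generated_quantities.csv")
  writeSummaryTable(gq, p)
  .msg(verbose, "compare: delta_%s EAP = %.3f [%.3f, %.3f] -> %s", term,
       gq@summary$EAP, gq@summary$CrI_low, gq@summary$CrI_high, p)
  list(generated_quantities = p)
}

.cmdReport <- function(config, outDir, verbose) {
  attrOrth <- readTraitDirection(config$attr_orth %||%
                                   file.path(outDir, "direction_attr_orth.json"))
  sexdimOrth <- readTraitDirection(config$sexdim_orth %||%
                                     file.path(outDir, "direction_sexdim_orth.json"))
  attrDir <- readTraitDirection(config$attr_direction %||%
                                  file.path(outDir, "direction_attr.json"))
  mascDir <- readTraitDirection(config$masc_direction %||%
                                  file.path(outDir, "direction_masc.json"))
  probe <- sampleFaces(config$n_probe %||% 200,
                       seed = childSeed(config$seed, "report"))
  lines <- character(0)
  checkPair <- function(target, nuisance, label) {
    drift <- numeric(0)
    slopeErr <- numeric(0)
    for (k in c(-3, -1, 1, 3)) {
      moved <- FaceSet(faceCoords(probe) +
                         matrix(k * unitStep(target), nFaces(probe), 100,
                                byrow = TRUE),
                       unname(faceSex(probe)))
      drift <- c(drift, max(abs(predictScore(nuisance, moved) -
                                  predictScore(nuisance, probe))))
      slopeErr <- c(slopeErr, max(abs((predictScore(target, moved) -
                                         predictScore(target, probe)) - k)))
    }
    ok <- max(drift) <= 1e-10 && max(slopeErr) <= 1e-8
    sprintf("dissociation (%s): %s  [max nuisance drift %.2e, max target slope error %.2e]",
            label, if (ok) "PASS" else "FAIL", max(drift), max(slopeErr))
  }
  lines <- c(lines,
             checkPair(attrOrth, mascDir, "attractiveness orthogonal to sexual dimorphism"),
             checkPair(sexdimOrth, attrDir, "sexual dimorphism orthogonal to attractiveness"))
  p <- file.path(outDir, "report.txt")
  writeLines(lines, p)
  if (verbose) for (l in lines) message(l)
  list(report = p)
}
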