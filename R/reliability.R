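#' @include AllClasses.R traitModel.R
NULL

#' @export
setMethod("show", "ReliabilityResult", function(object) {
  if (object@statistic == "cronbach_alpha") {
    cat(sprintf("Cronbach's alpha = %.3f (%d faces x %d raters)\n",
                object@estimate, object@nFaces, object@nRaters))
  } else {
    cat(sprintf("ICC(2,1) = %.3f, F(%d, %d) = %.2f, 95%% CI [%.3f, %.3f]\n",
                object@estimate, object@df1, object@df2, object@F,
                object@ciLow, object@ciHigh))
  }
})

#' Cronbach's alpha over raters
#'
#' Treats raters as items: \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)}
#' where \eqn{s_i^2} is the variance of rater i's ratings over faces and
#' \eqn{s_T^2} the variance of the per-face rating sums (sample variances,
#' n-1 denominator).
#'
#' @param ratings a [RatingMatrix-class]
#' @return a [ReliabilityResult-class]
#' @export
cronbachAlpha <- function(ratings) {
  stopifnot(is(ratings, "RatingMatrix"))
  validObject(ratings)
  v <- ratings@values
  k <- ncol(v)
  totVar <- stats::var(rowSums(v))
  if (!is.finite(totVar) || totVar == 0)
    stopf("degenerate ratings: zero variance of per-face rating sums")
  alpha <- k / (k - 1) * (1 - sum(apply(v, 2, stats::var)) / totVar)
  new("ReliabilityResult", statistic = "cronbach_alpha", estimate = alpha,
      nFaces = nrow(v), nRaters = k)
}

#' Intraclass correlation ICC(2,1): two-way random, single rater,
#' absolute agreement
#'
#' Computed from the two-way ANOVA mean squares of the complete faces x
#' raters matrix (faces as rows/targets, raters as columns/judges):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with the consistency F-test \eqn{F = MS_R / MS_E} on
#' \eqn{(n-1, (n-1)(k-1))} degrees of freedom and the Shrout-Fleiss
#' F-distribution 95\% confidence interval.
#'
#' @param ratings a [RatingMatrix-class]; the matrix must be complete.
#' @param conf confidence level for the interval (default 0.95).
#' @return a [ReliabilityResult-class] with estimate, F, df and CI.
#' @export
icc2 <- function(ratings, conf = 0.95) {
  stopifnot(is(ratings, "RatingMatrix"))
  validObject(ratings)
  v <- ratings@values
  if (any(is.na(v)))
    stopf("ICC(2,1) requires a complete rating matrix (no imputation)")
  n <- nrow(v); k <- ncol(v)
  storage.mode(v) <- "double"
  grand <- mean(v)
  rowM <- rowMeans(v); colM <- colMeans(v)
  SSR <- k * sum((rowM - grand)^2)            # between faces (rows)
  SSC <- n * sum((colM - grand)^2)            # between raters (columns)
  SST <- sum((v - grand)^2)
  SSE <- SST - SSR - SSC                      # residual
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  Fstat <- MSR / MSE
  df1 <- as.integer(n - 1)
  df2 <- as.integer((n - 1) * (k - 1))
  # Shrout & Fleiss (1979) interval for ICC(2,1)
  a <- 1 - conf
  Fj <- MSC / MSE
  vn <- (k - 1) * (n - 1) *
    (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  vdf <- vn / vd
  FL <- stats::qf(1 - a / 2, n - 1, vdf)
  FU <- stats::qf(1 - a / 2, vdf, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  new("ReliabilityResult", statistic = "icc2", estimate = icc, F = Fstat,
      df1 = df1, df2 = df2, ciLow = lo, ciHigh = hi,
      nFaces = as.integer(n), nRaters = as.integer(k))
}

#' @export
setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("rho (EAP) = %.3f, 95%% CrI [%.3f, %.3f], n = %s\n",
              object@rhoEap, object@criLow, object@criHigh,
              object@meta$n %||% "?"))
  if (!is.na(object@deltaEap))
    cat(sprintf("delta rho (EAP) = %.3f, 95%% CrI [%.3f, %.3f]\n",
                object@deltaEap, object@deltaLow, object@deltaHigh))
})

#' @describeIn posteriorDraws rho draws of a CorrelationResult
#' @export
setMethod("posteriorDraws", "CorrelationResult", function(x) x@rhoDraws)

# Exact posterior draws of rho from the bivariate-normal model under the
# Jeffreys prior p(mu, Sigma) ~ |Sigma|^(-3/2): Sigma | data is
# inverse-Wishart(n - 1, S) with S the centered cross-product matrix, so
# rho draws are iid transforms of Wishart draws (for 2x2, the inverse is the
# rescaled adjugate, hence rho = -W12 / sqrt(W11 W22)).
.sampleRho <- function(x, y, rankTransform, draws, seed) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("degenerate input: constant vector has no defined correlation")
  if (rankTransform) {
    x <- rank(x); y <- rank(y)
  }
  xy <- cbind(x, y)
  n <- nrow(xy)
  S <- crossprod(sweep(xy, 2, colMeans(xy)))
  # minimal ridge keeps S invertible when the inputs are exactly collinear
  S <- S + diag(2) * 1e-10 * (S[1, 1] + S[2, 2]) / 2
  withLocalSeed(seed, {
    W <- stats::rWishart(draws, df = n - 1, Sigma = solve(S))
    -W[1, 2, ] / sqrt(W[1, 1, ] * W[2, 2, ])
  })
}

#' Bayesian (rank) correlation with credible interval
#'
#' Posterior over the correlation rho of a bivariate normal model under the
#' Jeffreys prior, sampled exactly (iid draws from the inverse-Wishart
#' posterior of the covariance matrix). With \code{rankTransform = TRUE}
#' (default) the data are rank-transformed first, so rho emulates Spearman's
#' rank correlation; the credible interval is the central 95\% interval of
#' the posterior draws.
#'
#' @param x,y equal-length numeric vectors of per-face scores.
#' @param rankTransform rank-transform the inputs first (default TRUE).
#' @param draws posterior draws to keep (default 10000).
#' @param seed integer seed for reproducible sampling.
#' @return a [CorrelationResult-class]
#' @export
bayesianCorrelation <- function(x, y, rankTransform = TRUE, draws = 10000,
                                seed = 1) {
  r <- .sampleRho(x, y, rankTransform, draws, seed)
  q <- unname(stats::quantile(r, c(0.025, 0.975)))
  new("CorrelationResult", rhoEap = mean(r), criLow = q[1], criHigh = q[2],
      rhoDraws = r,
      meta = list(n = length(x), rank_transform = rankTransform,
                  draws = length(r), seed = seed,
                  formulation = "bivariate normal, Jeffreys prior, exact inverse-Wishart posterior"))
}

#' Posterior difference of two independent correlations
#'
#' Fits [bayesianCorrelation()] to two independent samples and forms the
#' difference posterior by draw-wise subtraction (a - b), reporting its EAP
#' and central 95\% credible interval alongside sample a's correlation.
#'
#' @param xa,ya first sample.
#' @param xb,yb second sample.
#' @inheritParams bayesianCorrelation
#' @return a [CorrelationResult-class] with the delta slots populated
#'   (rho slots describe sample a).
#' @export
correlationDifference <- function(xa, ya, xb, yb, rankTransform = TRUE,
                                  draws = 10000, seed = 1) {
  ra <- .sampleRho(xa, ya, rankTransform, draws, childSeed(seed, "corrA"))
  rb <- .sampleRho(xb, yb, rankTransform, draws, childSeed(seed, "corrB"))
  n <- min(length(ra), length(rb))
  d <- ra[seq_len(n)] - rb[seq_len(n)]
  qa <- unname(stats::quantile(ra, c(0.025, 0.975)))
  qd <- unname(stats::quantile(d, c(0.025, 0.975)))
  new("CorrelationResult", rhoEap = mean(ra), criLow = qa[1], criHigh = qa[2],
      rhoDraws = ra, deltaEap = mean(d), deltaLow = qd[1], deltaHigh = qd[2],
      deltaDraws = d,
      meta = list(n = c(a = length(xa), b = length(xb)),
                  rank_transform = rankTransform, draws = n, seed = seed,
                  formulation = "bivariate normal, Jeffreys prior, exact inverse-Wishart posterior"))
}

#' Write reliability / correlation results as a delimited summary table
#'
#' @param results a list of [ReliabilityResult-class] and/or
#'   [CorrelationResult-class] objects.
#' @param path output file
#' @return invisibly, the path
#' @export
writeReliabilityTable <- function(results, path) {
  rows <- lapply(results, function(r) {
    if (is(r, "ReliabilityResult")) {
      data.frame(statistic = r@statistic, estimate = r@estimate,
                 ci_low = r@ciLow, ci_high = r@ciHigh, F = r@F,
                 df1 = r@df1, df2 = r@df2, n_faces = r@nFaces,
                 n_raters = r@nRaters)
    } else {
      data.frame(statistic = "rho", estimate = r@rhoEap, ci_low = r@criLow,
                 ci_high = r@criHigh, F = NA_real_, df1 = NA_integer_,
                 df2 = NA_integer_, n_faces = NA_integer_,
                 n_raters = NA_integer_)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
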