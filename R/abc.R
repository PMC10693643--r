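#' Robust standardisation of the reference table against an observed vector
#'
#' Each statistic column is transformed by (x - median)/MAD of the reference
#' simulations; the observed vector is transformed with the same constants.
#' Columns with zero variance are dropped with a warning; columns with zero
#' MAD but positive variance fall back to the standard deviation as scale.
#'
#' @param refStats numeric matrix of reference statistics (rows =
#'   simulations).
#' @param observed named numeric vector of observed statistics (same
#'   columns).
#' @return List with \code{ref} (standardised matrix), \code{obs}
#'   (standardised observed), \code{kept} (column indices retained),
#'   \code{center}, \code{scale}.
#' @export
standardizeStats <- function(refStats, observed) {
  stopifnot(is.matrix(refStats), ncol(refStats) == length(observed))
  ctr <- apply(refStats, 2, stats::median)
  sdv <- apply(refStats, 2, stats::sd)
  mad <- apply(refStats, 2, stats::mad)
  keep <- which(sdv > 0)
  if (length(keep) == 0L)
    stop("inference error: all statistic columns have zero variance")
  if (length(keep) < ncol(refStats))
    warning("dropping zero-variance statistic columns: ",
            paste(colnames(refStats)[-keep], collapse = ", "))
  scl <- ifelse(mad > 0, mad, sdv)[keep]
  ref <- sweep(sweep(refStats[, keep, drop = FALSE], 2, ctr[keep]), 2, scl, "/")
  obs <- (as.numeric(observed)[keep] - ctr[keep]) / scl
  list(ref = ref, obs = obs, kept = keep, center = ctr[keep], scale = scl)
}

#' Rejection step: accept the closest simulations
#'
#' Euclidean distance in standardised statistic space; the
#' \code{ceiling(tolerance * n)} closest rows are accepted, ties broken by
#' row order.
#'
#' @param refStd standardised reference matrix.
#' @param obsStd standardised observed vector.
#' @param tolerance accepted fraction in (0, 1].
#' @return List with \code{accepted} (row indices in acceptance order) and
#'   \code{distances} (their distances).
#' @export
rejectionSample <- function(refStd, obsStd, tolerance) {
  n <- nrow(refStd)
  if (tolerance * n < 1) stop("inference error: tolerance * n < 1")
  k <- ceiling(tolerance * n)
  d <- sqrt(colSums((t(refStd) - obsStd)^2))
  o <- order(d)[seq_len(k)]
  list(accepted = o, distances = d[o])
}

#' Logit transform with bounds, and its inverse
#'
#' \code{logitTransform} maps (lower, upper) to the real line via
#' \eqn{y = \log((x - l)/(u - x))}; values exactly on a boundary are nudged
#' inward by 1e-9 (upper - lower). \code{logitInverse} maps any real y back
#' inside the bounds.
#'
#' @param x values in [lower, upper].
#' @param lower,upper finite bounds, lower < upper.
#' @return Transformed values.
#' @export
logitTransform <- function(x, lower, upper) {
  stopifnot(lower < upper)
  if (any(x < lower | x > upper, na.rm = TRUE))
    stop("invalid input: values outside the transform bounds")
  eps <- 1e-9 * (upper - lower)
  x <- pmin(pmax(x, lower + eps), upper - eps)
  log((x - lower) / (upper - x))
}

#' @rdname logitTransform
#' @param y real values to map back into (lower, upper).
#' @export
logitInverse <- function(y, lower, upper) {
  stopifnot(lower < upper)
  lower + (upper - lower) / (1 + exp(-y))
}

# Epanechnikov weights on accepted distances, as in standard regression-ABC:
# w_i = 1 - (d_i / d_max)^2, with a uniform fallback when degenerate.
epanechnikovWeights <- function(d) {
  dm <- max(d)
  w <- if (dm > 0) 1 - (d / dm)^2 else rep(1, length(d))
  if (sum(w) <= 0) w <- rep(1, length(d))
  w / sum(w)
}

# One weighted nnet regression fit, averaged over re-seeded restarts.
# Returns fitted values on the training rows and the prediction at obs.
nnetFit <- function(xTrain, yTrain, w, xObs, hidden, restarts, decay = 1) {
  fitSum <- rep(0, nrow(xTrain)); obsSum <- 0; okFits <- 0L
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      nnet::nnet(x = xTrain, y = yTrain, weights = w, size = hidden,
                 linout = TRUE, decay = decay, maxit = 500, trace = FALSE,
                 MaxNWts = 10000),
      error = function(e) NULL)
    if (is.null(fit)) next
    fitSum <- fitSum + as.numeric(stats::predict(fit, xTrain))
    obsSum <- obsSum + as.numeric(stats::predict(fit, matrix(xObs, nrow = 1)))
    okFits <- okFits + 1L
  }
  if (okFits == 0L) stop("regression failure")
  list(fitted = fitSum / okFits, obsPred = obsSum / okFits)
}

# Weighted local-linear fit; same return contract as nnetFit.
loclinearFit <- function(xTrain, yTrain, w, xObs) {
  X <- cbind(1, xTrain)
  fit <- stats::lm.wfit(X, yTrain, w)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(fitted = as.numeric(X %*% beta),
       obsPred = as.numeric(c(1, xObs) %*% beta))
}

# Conditional-mean regression plus a heteroscedastic correction: a second
# regression of log squared residuals rescales each accepted draw by
# sigma(s_obs)/sigma(s_i), as in standard regression-ABC. The variance
# ratio is clamped to [1/20, 20] as a numerical guard against exploding
# corrections when residuals are near zero.
regressOne <- function(xTrain, yTrain, w, xObs, engine, ...) {
  m <- engine(xTrain, yTrain, w, xObs, ...)
  resid <- yTrain - m$fitted
  logSq <- log(resid^2 + 1e-12)
  v <- engine(xTrain, logSq, w, xObs, ...)
  sigmaI <- exp(0.5 * v$fitted)
  sigmaObs <- exp(0.5 * v$obsPred)
  ratio <- pmin(pmax(sigmaObs / pmax(sigmaI, 1e-12), 0.05), 20)
  m$obsPred + (yTrain - m$fitted) * ratio
}

#' Regression adjustment of accepted parameters
#'
#' Parameters are logit-transformed to their prior bounds, regressed on the
#' standardised statistics over the accepted simulations (single
#' hidden-layer feed-forward net with sigmoidal activation and weight
#' decay, averaged over re-seeded restarts, or weighted local-linear
#' regression), and each accepted draw is corrected toward the observed
#' statistics with a heteroscedastic variance rescaling:
#' theta* = m(s_obs) + (theta - m(s_i)) sigma(s_obs)/sigma(s_i), where
#' sigma is fitted by a second regression on log squared residuals.
#' Epanechnikov kernel
#' weights on distance are used both in the fit and in the posterior
#' summaries. The back-transform confines all adjusted draws to the prior
#' support. On regression failure the method falls back to plain rejection
#' with a warning.
#'
#' @param acceptedParams numeric matrix of accepted parameter draws (natural
#'   scale), columns \code{paramNames()}.
#' @param acceptedStats standardised statistics of the accepted rows.
#' @param obsStd standardised observed vector.
#' @param distances acceptance distances (for the kernel weights).
#' @param prior the \code{PriorSpec} giving the transform bounds.
#' @param cfg an \code{ABCConfig}.
#' @param constants \code{ModelConstants} for the years-BP conversion.
#' @return A \code{PosteriorResult}.
#' @export
regressionAdjust <- function(acceptedParams, acceptedStats, obsStd, distances,
                             prior = defaultPriors(), cfg = abcConfig(),
                             constants = modelConstants()) {
  validObject(cfg)
  if (nrow(acceptedParams) == 0L) stop("inference error: empty accepted set")
  bounds <- priorBounds(prior)
  # plain rejection keeps uniform weights so its summaries are the raw
  # accepted-sample quantiles
  w <- if (cfg@method == "rejection") {
    rep(1 / length(distances), length(distances))
  } else {
    epanechnikovWeights(distances)
  }
  adj <- matrix(NA_real_, nrow(acceptedParams), ncol(acceptedParams),
                dimnames = dimnames(acceptedParams))
  for (pn in paramNames()) {
    lo <- bounds$lower[[pn]]; up <- bounds$upper[[pn]]
    thetaT <- logitTransform(acceptedParams[, pn], lo, up)
    if (cfg@method == "rejection") {
      adj[, pn] <- acceptedParams[, pn]
      next
    }
    res <- tryCatch({
      if (cfg@method == "neuralnet") {
        withSeed(cfg@seed + match(pn, paramNames()),
                 regressOne(acceptedStats, thetaT, w, obsStd, nnetFit,
                            hidden = cfg@hiddenUnits, restarts = cfg@restarts,
                            decay = cfg@decay))
      } else {
        regressOne(acceptedStats, thetaT, w, obsStd, loclinearFit)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      warning("regression adjustment failed for ", pn,
              "; falling back to rejection")
      adj[, pn] <- acceptedParams[, pn]
    } else {
      adj[, pn] <- logitInverse(res, lo, up)
    }
  }
  summarisePosterior(adj, w, cfg, constants)
}

summarisePosterior <- function(samples, weights, cfg, constants) {
  qs <- t(apply(samples, 2, function(x)
    weightedQuantile(x, weights, c(0.5, 0.025, 0.975))))
  summary <- data.frame(parameter = colnames(samples),
                        median = qs[, 1], q2.5 = qs[, 2], q97.5 = qs[, 3],
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  gs <- summary[summary$parameter == "gen_split", ]
  yearsBP <- c(median = gs$median, q2.5 = gs$q2.5, q97.5 = gs$q97.5) *
    constants@generationTimeYears
  new("PosteriorResult", samples = samples, weights = weights,
      summary = summary, yearsBP = yearsBP, method = cfg@method,
      tolerance = cfg@tolerance)
}

#' Estimate the posterior for an observed summary vector
#'
#' Composition of \code{\link{standardizeStats}},
#' \code{\link{rejectionSample}} and \code{\link{regressionAdjust}}. The
#' split generation is additionally reported in years BP (x generation
#' time).
#'
#' @param reference a \code{ReferenceTable}.
#' @param observed named numeric summary vector (46 registry statistics).
#' @param cfg an \code{ABCConfig}.
#' @param prior \code{PriorSpec} used for the parameter transforms; by
#'   default read from the reference provenance, else
#'   \code{defaultPriors()}.
#' @param constants \code{ModelConstants} (years-BP conversion).
#' @return A \code{PosteriorResult}.
#' @export
estimatePosterior <- function(reference, observed, cfg = abcConfig(),
                              prior = NULL, constants = modelConstants()) {
  stopifnot(is(reference, "ReferenceTable"))
  validObject(cfg)
  if (is.null(prior)) {
    prior <- reference@provenance$prior
    if (is.null(prior)) prior <- defaultPriors()
  }
  std <- standardizeStats(refStats(reference), observed)
  rej <- rejectionSample(std$ref, std$obs, cfg@tolerance)
  regressionAdjust(refParams(reference)[rej$accepted, , drop = FALSE],
                   std$ref[rej$accepted, , drop = FALSE],
                   std$obs, rej$distances, prior, cfg, constants)
}
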