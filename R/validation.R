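#' Leave-out pseudo-observed validation of the ABC estimator
#'
#' Randomly selects \code{nHoldout} reference rows; each row's statistics
#' are treated as the observed data, the row itself is excluded from the
#' reference (leave-one-out, avoiding the distance-zero self match), the
#' posterior is estimated, and the posterior median is compared with the
#' row's true parameters. Reports per-parameter Mean Absolute Error, Mean
#' Squared Error, Root Mean Squared Error of the posterior medians, and the
#' frequency with which the truth falls inside the [2.5, 97.5] percentile
#' interval.
#'
#' @param reference a \code{ReferenceTable}.
#' @param nHoldout number of pseudo-observed rows (< number of simulations).
#' @param cfg an \code{ABCConfig}.
#' @param seed integer seed for the holdout selection.
#' @param estimator optional estimator override with signature
#'   \code{function(reference, observed, cfg)} returning a
#'   \code{PosteriorResult}; defaults to \code{\link{estimatePosterior}}.
#' @return A \code{ValidationReport}.
#' @export
holdoutValidate <- function(reference, nHoldout, cfg = abcConfig(), seed = 1L,
                            estimator = NULL) {
  stopifnot(is(reference, "ReferenceTable"))
  n <- nrow(reference)
  if (nHoldout >= n) stop("invalid input: nHoldout must be < number of simulations")
  if (nHoldout < 1) stop("invalid input: nHoldout must be >= 1")
  if (is.null(estimator)) estimator <- estimatePosterior
  rows <- withSeed(seed, sample.int(n, nHoldout))
  pn <- paramNames()
  med <- matrix(NA_real_, nHoldout, length(pn), dimnames = list(NULL, pn))
  cov <- matrix(NA, nHoldout, length(pn), dimnames = list(NULL, pn))
  for (k in seq_len(nHoldout)) {
    r <- rows[k]
    truth <- refParams(reference)[r, ]
    obs <- refStats(reference)[r, ]
    sub <- new("ReferenceTable",
               params = refParams(reference)[-r, , drop = FALSE],
               stats = refStats(reference)[-r, , drop = FALSE],
               provenance = reference@provenance)
    post <- estimator(sub, obs, cfg)
    s <- posteriorSummary(post)
    rownames(s) <- s$parameter
    med[k, ] <- s[pn, "median"]
    cov[k, ] <- truth[pn] >= s[pn, "q2.5"] & truth[pn] <= s[pn, "q97.5"]
  }
  truths <- refParams(reference)[rows, , drop = FALSE]
  err <- med - truths
  tb <- data.frame(
    parameter = pn,
    mae = colMeans(abs(err)),
    mse = colMeans(err^2),
    rmse = sqrt(colMeans(err^2)),
    coverage = colMeans(cov),
    stringsAsFactors = FALSE
  )
  rownames(tb) <- NULL
  new("ValidationReport", table = tb, nHoldout = as.integer(nHoldout))
}

#' Replay the tolerance/method selection grid
#'
#' Runs \code{\link{holdoutValidate}} for every combination of the supplied
#' tolerances and methods under a common holdout seed and reports the mean
#' prediction error per setting: the average over parameters of MSE scaled
#' by the variance of the holdout truths (so parameters on different
#' natural scales contribute comparably).
#'
#' @param reference a \code{ReferenceTable}.
#' @param tolerances numeric vector of accepted fractions.
#' @param methods character vector of adjustment methods.
#' @param nHoldout holdouts per setting.
#' @param cfg base \code{ABCConfig} (its tolerance/method are overridden).
#' @param seed integer seed shared by every setting.
#' @return data.frame with one row per setting: \code{tolerance},
#'   \code{method}, \code{meanScaledError}, plus the per-parameter report
#'   columns.
#' @export
compareTolerances <- function(reference, tolerances, methods, nHoldout,
                              cfg = abcConfig(), seed = 1L) {
  if (length(tolerances) < 1L || length(methods) < 1L)
    stop("invalid input: at least one setting required")
  grid <- expand.grid(tolerance = tolerances, method = methods,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfgI <- abcConfig(tolerance = grid$tolerance[i], method = grid$method[i],
                      hiddenUnits = cfg@hiddenUnits, restarts = cfg@restarts,
                      decay = cfg@decay, seed = cfg@seed)
    rep <- holdoutValidate(reference, nHoldout, cfgI, seed = seed)
    tb <- validationTable(rep)
    truthVar <- apply(refParams(reference), 2, stats::var)[tb$parameter]
    data.frame(tolerance = grid$tolerance[i], method = grid$method[i],
               meanScaledError = mean(tb$mse / truthVar),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
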