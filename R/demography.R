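#' Per-generation exponential growth/decay rate of a branch
#'
#' Moving backwards in time, each extant population is initialised at its
#' present-day diploid size and shrinks (or grows) exponentially so that it
#' reaches its at-split size exactly at the split generation:
#' \deqn{\alpha = \log(N_{present}/N_{split}) / g_{split}.}
#' The sign is positive when the population grew forwards in time toward the
#' present.
#'
#' @param nPresent diploid size at generation 0 (> 0).
#' @param nSplit diploid size at the split generation (> 0).
#' @param genSplit split generation (> 0).
#' @return The per-generation exponential rate (numeric scalar).
#' @examples
#' growthRate(1000, 1000, 100)   # 0: constant size
#' growthRate(20000, 5000, 118)  # log(4)/118
#' @export
growthRate <- function(nPresent, nSplit, genSplit) {
  if (any(c(nPresent, nSplit, genSplit) <= 0) || anyNA(c(nPresent, nSplit, genSplit)))
    stop("invalid parameter: all arguments to growthRate must be > 0")
  log(nPresent / nSplit) / genSplit
}

#' Diploid size of a branch at a time in the past
#'
#' Evaluates the backwards-in-time trajectory \eqn{N(t) = N_{present}
#' e^{-\alpha t}} of one extant branch for \eqn{0 \le t \le g_{split}}.
#'
#' @param params a \code{SplitModelParams}.
#' @param pop \code{"cab"} or \code{"moz"}.
#' @param t time in generations before present.
#' @return Diploid size at time \code{t}.
#' @export
branchSizeAt <- function(params, pop = c("cab", "moz"), t) {
  pop <- match.arg(pop)
  np <- if (pop == "cab") params@nCabPresent else params@nMozPresent
  ns <- if (pop == "cab") params@nCabSplit else params@nMozSplit
  a <- growthRate(np, ns, params@genSplit)
  np * exp(-a * t)
}

#' Build the backwards-in-time event timeline of the clean-split model
#'
#' Three epochs, ordered backwards from the present: (i) at t = 0 the two
#' populations start at their present-day sizes with exponential rates
#' \code{growthRate()}; (ii) at the split generation the two branches merge
#' into a single ancestral deme (lineages coalesce freely) whose size is the
#' sum of the two at-split branch sizes; (iii) at the fixed ancestral-change
#' generation the ancestral deme instantaneously changes to the fixed
#' ancestral size.
#'
#' @param params a valid \code{SplitModelParams}.
#' @param constants a \code{ModelConstants}; \code{params@genSplit} must be
#'   strictly smaller than \code{constants@genAncestralChange}.
#' @return A \code{DemographyTimeline}.
#' @export
buildTimeline <- function(params, constants = modelConstants()) {
  validObject(params)
  validObject(constants)
  if (params@genSplit >= constants@genAncestralChange)
    stop("invalid parameter: gen_split (", params@genSplit,
         ") must be < genAncestralChange (", constants@genAncestralChange, ")")
  aCab <- growthRate(params@nCabPresent, params@nCabSplit, params@genSplit)
  aMoz <- growthRate(params@nMozPresent, params@nMozSplit, params@genSplit)
  ev <- data.frame(
    time = c(0, 0, params@genSplit, constants@genAncestralChange),
    type = c("present", "present", "merge", "size_change"),
    deme = c("CAB", "MOZ", "ANC", "ANC"),
    size = c(params@nCabPresent, params@nMozPresent,
             params@nCabSplit + params@nMozSplit, constants@nAncestralFixed),
    rate = c(aCab, aMoz, 0, 0),
    stringsAsFactors = FALSE
  )
  new("DemographyTimeline", events = ev, params = params, constants = constants)
}

#' Sample parameter sets from the prior
#'
#' Draws \code{n} independent parameter sets. Uniform parameters are drawn
#' uniformly on [lower, upper]; log-uniform parameters uniformly on the log
#' scale. Draws are reproducible bit-for-bit under a fixed seed and each row
#' satisfies the model invariants.
#'
#' @param prior a \code{PriorSpec}.
#' @param n number of draws (>= 0).
#' @param seed integer seed.
#' @return data.frame with \code{n} rows and columns \code{paramNames()}.
#' @export
samplePrior <- function(prior, n, seed = 1L) {
  validObject(prior)
  if (n < 0) stop("n must be >= 0")
  tb <- prior@table
  rownames(tb) <- tb$parameter
  tb <- tb[paramNames(), ]
  out <- withSeed(seed, {
    draws <- lapply(seq_len(nrow(tb)), function(i) {
      if (n == 0L) return(numeric(0))
      if (tb$dist[i] == "uniform") {
        stats::runif(n, tb$lower[i], tb$upper[i])
      } else {
        exp(stats::runif(n, log(tb$lower[i]), log(tb$upper[i])))
      }
    })
    names(draws) <- tb$parameter
    as.data.frame(draws, stringsAsFactors = FALSE)
  })
  if (n == 0L) out <- out[0, , drop = FALSE]
  out
}

#' Report a split generation in years before present
#'
#' Multiplies generations by the generation time; used only at reporting.
#'
#' @param generations numeric vector of generation counts.
#' @param constants a \code{ModelConstants}.
#' @return years BP.
#' @export
generationsToYearsBP <- function(generations, constants = modelConstants()) {
  generations * constants@generationTimeYears
}
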