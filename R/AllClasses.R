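#' @useDynLib splitABC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Names of the five free demographic parameters
#'
#' The clean-split model has five free parameters: the present-day and
#' at-split diploid effective sizes of each population (CAB-like and
#' MOZ-like), and the split generation. All sizes are diploid; times are in
#' generations before present.
#'
#' @return Character vector of length 5, in canonical order.
#' @export
paramNames <- function() {
  c("n_cab_present", "n_cab_split", "n_moz_present", "n_moz_split", "gen_split")
}

#' Fixed constants of the clean-split model
#'
#' Holds the fixed (non-inferred) quantities: the diploid size the merged
#' ancestral population changes to instantaneously, the generation of that
#' change, the per-bp per-generation mutation rate, and the generation time
#' in years used only when reporting times in years BP.
#'
#' @slot nAncestralFixed diploid size after the ancestral step change.
#' @slot genAncestralChange generation (backwards from present) of the change.
#' @slot mutationRate per-bp per-generation mutation rate.
#' @slot generationTimeYears years per generation, used at reporting only.
#' @export
setClass("ModelConstants", representation(
  nAncestralFixed = "numeric",
  genAncestralChange = "numeric",
  mutationRate = "numeric",
  generationTimeYears = "numeric"
))

setValidity("ModelConstants", function(object) {
  msg <- character()
  if (length(object@nAncestralFixed) != 1L || object@nAncestralFixed <= 0)
    msg <- c(msg, "nAncestralFixed must be a single positive number")
  if (length(object@genAncestralChange) != 1L || object@genAncestralChange <= 0)
    msg <- c(msg, "genAncestralChange must be a single positive number")
  if (object@mutationRate < 0) msg <- c(msg, "mutationRate must be >= 0")
  if (object@generationTimeYears <= 0) msg <- c(msg, "generationTimeYears must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct the model constants
#'
#' Defaults are the fixed ancestral history (diploid size 12,000 reached
#' instantaneously at generation 7586), a mutation rate of 1.25e-8 per bp per
#' generation, and a generation time of 27 years.
#'
#' @param nAncestralFixed diploid ancestral size after the step change.
#' @param genAncestralChange generation of the ancestral step change.
#' @param mutationRate per-bp per-generation mutation rate.
#' @param generationTimeYears years per generation (reporting only).
#' @return A \code{ModelConstants} object.
#' @export
modelConstants <- function(nAncestralFixed = 12000,
                           genAncestralChange = 7586,
                           mutationRate = 1.25e-8,
                           generationTimeYears = 27) {
  new("ModelConstants",
      nAncestralFixed = as.numeric(nAncestralFixed),
      genAncestralChange = as.numeric(genAncestralChange),
      mutationRate = as.numeric(mutationRate),
      generationTimeYears = as.numeric(generationTimeYears))
}

#' Free parameters of the clean-split model
#'
#' @slot nCabPresent diploid effective size of the CAB-like population at
#'   generation 0.
#' @slot nCabSplit diploid effective size of the CAB-like branch at the split
#'   generation.
#' @slot nMozPresent,nMozSplit as above for the MOZ-like population.
#' @slot genSplit generation (backwards from present) at which the two
#'   populations merge into one ancestral population.
#' @export
setClass("SplitModelParams", representation(
  nCabPresent = "numeric",
  nCabSplit = "numeric",
  nMozPresent = "numeric",
  nMozSplit = "numeric",
  genSplit = "numeric"
))

setValidity("SplitModelParams", function(object) {
  v <- c(object@nCabPresent, object@nCabSplit, object@nMozPresent,
         object@nMozSplit, object@genSplit)
  if (length(v) != 5L || anyNA(v)) return("all five parameters must be single non-NA numbers")
  if (any(v <= 0)) return("all sizes and the split generation must be > 0")
  TRUE
})

#' Construct a clean-split parameter set
#'
#' @param nCabPresent,nCabSplit,nMozPresent,nMozSplit diploid effective sizes
#'   (> 0).
#' @param genSplit split generation (> 0); must be earlier (smaller) than the
#'   ancestral step-change generation of the constants it is used with.
#' @return A \code{SplitModelParams} object.
#' @export
splitModelParams <- function(nCabPresent, nCabSplit, nMozPresent, nMozSplit, genSplit) {
  new("SplitModelParams",
      nCabPresent = as.numeric(nCabPresent), nCabSplit = as.numeric(nCabSplit),
      nMozPresent = as.numeric(nMozPresent), nMozSplit = as.numeric(nMozSplit),
      genSplit = as.numeric(genSplit))
}

#' Convert a parameter set to a named numeric vector
#' @param params A \code{SplitModelParams}.
#' @return Named numeric vector in \code{paramNames()} order.
#' @export
paramsToVector <- function(params) {
  stopifnot(is(params, "SplitModelParams"))
  stats::setNames(c(params@nCabPresent, params@nCabSplit, params@nMozPresent,
                    params@nMozSplit, params@genSplit), paramNames())
}

#' Build a parameter set from a named vector or one-row data frame
#' @param x named numeric vector or one-row data frame carrying
#'   \code{paramNames()} entries.
#' @return A \code{SplitModelParams}.
#' @export
paramsFromVector <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, paramNames()])
  x <- x[paramNames()]
  splitModelParams(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]])
}

#' Prior specification for the five model parameters
#'
#' One row per parameter with a distribution kind (\code{"uniform"} or
#' \code{"loguniform"}) and finite bounds.
#'
#' @slot table data.frame with columns \code{parameter}, \code{dist},
#'   \code{lower}, \code{upper}.
#' @export
setClass("PriorSpec", representation(table = "data.frame"))

setValidity("PriorSpec", function(object) {
  tb <- object@table
  need <- c("parameter", "dist", "lower", "upper")
  if (!all(need %in% names(tb))) return("prior table must have parameter/dist/lower/upper")
  if (!setequal(tb$parameter, paramNames())) return("prior must cover exactly the five model parameters")
  if (!all(tb$dist %in% c("uniform", "loguniform"))) return("dist must be uniform or loguniform")
  if (!all(is.finite(tb$lower)) || !all(is.finite(tb$upper))) return("bounds must be finite")
  if (!all(tb$lower < tb$upper)) return("lower must be < upper")
  if (any(tb$dist == "loguniform" & tb$lower <= 0)) return("loguniform bounds must be > 0")
  TRUE
})

#' Default priors for the clean-split model
#'
#' Log-uniform on all four diploid sizes over [100, 100000] and uniform on
#' the split generation over [10, 7000]; the split upper bound stays below
#' the fixed ancestral-change generation (7586). Fully overridable via the
#' run configuration.
#'
#' @return A \code{PriorSpec}.
#' @export
defaultPriors <- function() {
  new("PriorSpec", table = data.frame(
    parameter = paramNames(),
    dist = c("loguniform", "loguniform", "loguniform", "loguniform", "uniform"),
    lower = c(100, 100, 100, 100, 10),
    upper = c(1e5, 1e5, 1e5, 1e5, 7000),
    stringsAsFactors = FALSE
  ))
}

#' Construct a prior specification
#'
#' @param table data.frame with columns \code{parameter}, \code{dist}
#'   (\code{"uniform"} or \code{"loguniform"}), \code{lower}, \code{upper};
#'   one row per entry of \code{paramNames()}.
#' @param constants \code{ModelConstants} used to check that the split-time
#'   prior stays below the ancestral change generation.
#' @return A \code{PriorSpec}.
#' @export
priorSpec <- function(table, constants = modelConstants()) {
  obj <- new("PriorSpec", table = as.data.frame(table, stringsAsFactors = FALSE))
  gs <- obj@table[obj@table$parameter == "gen_split", ]
  if (gs$upper >= constants@genAncestralChange)
    stop("gen_split prior upper bound must be < genAncestralChange (",
         constants@genAncestralChange, ")")
  obj
}

#' Prior bounds as a named list
#' @param prior A \code{PriorSpec}.
#' @return List with \code{lower} and \code{upper} named vectors in
#'   \code{paramNames()} order.
#' @export
priorBounds <- function(prior) {
  tb <- prior@table
  rownames(tb) <- tb$parameter
  tb <- tb[paramNames(), ]
  list(lower = stats::setNames(tb$lower, tb$parameter),
       upper = stats::setNames(tb$upper, tb$parameter))
}

#' Backwards-in-time event timeline of the clean-split model
#'
#' Three epochs: present-day sizes with per-branch exponential rates, the
#' merge of both branches at the split generation, and the instantaneous
#' ancestral size change. Produced by \code{\link{buildTimeline}}.
#'
#' @slot events data.frame of ordered events (time, type, deme, size, rate).
#' @slot params the generating \code{SplitModelParams}.
#' @slot constants the \code{ModelConstants} used.
#' @export
setClass("DemographyTimeline", representation(
  events = "data.frame",
  params = "SplitModelParams",
  constants = "ModelConstants"
))

setValidity("DemographyTimeline", function(object) {
  tms <- object@events$time
  if (is.unsorted(tms)) return("events must be ordered in time")
  TRUE
})

#' Recombination map with physical and genetic coordinates
#'
#' Knot positions in bp with per-interval rates (cM/Mb) and cumulative
#' genetic positions (cM). Queries between knots interpolate linearly;
#' queries beyond the last knot extrapolate at the final rate.
#'
#' @slot pos knot physical positions (bp), strictly increasing.
#' @slot rateCMMb per-interval recombination rate in cM/Mb; entry i applies
#'   from pos[i] (the last entry extrapolates past the final knot).
#' @slot cm cumulative genetic position (cM) at each knot, non-decreasing.
#' @export
setClass("RecombMap", representation(
  pos = "numeric", rateCMMb = "numeric", cm = "numeric"
))

setValidity("RecombMap", function(object) {
  if (length(object@pos) < 1L) return("map needs at least one knot")
  if (any(diff(object@pos) <= 0)) return("positions must be strictly increasing")
  if (any(diff(object@cm) < 0)) return("cumulative cM must be non-decreasing")
  if (any(object@rateCMMb < 0)) return("rates must be >= 0")
  if (length(object@pos) != length(object@cm) ||
      length(object@pos) != length(object@rateCMMb))
    return("pos, rateCMMb and cm must have equal length")
  TRUE
})

#' Genome/sampling configuration for a simulation
#'
#' @slot sequenceLength simulated sequence length in bp.
#' @slot recombMap \code{RecombMap} giving variable recombination rates.
#' @slot mutationRate per-bp per-generation mutation rate.
#' @slot samplesPerPop diploid sample count per population.
#' @export
setClass("GenomeConfig", representation(
  sequenceLength = "numeric",
  recombMap = "RecombMap",
  mutationRate = "numeric",
  samplesPerPop = "integer"
))

setValidity("GenomeConfig", function(object) {
  if (object@sequenceLength <= 0) return("sequenceLength must be > 0")
  if (object@samplesPerPop < 1L) return("samplesPerPop must be >= 1")
  if (object@mutationRate < 0) return("mutationRate must be >= 0")
  TRUE
})

#' Construct a genome configuration
#'
#' @param sequenceLength sequence length in bp (default 10 Mb desk scale).
#' @param recombMap a \code{RecombMap}; default is the bundled variable-rate
#'   10 Mb desk map (see \code{\link{deskRecombMap}}).
#' @param mutationRate per-bp per-generation rate; default from
#'   \code{\link{modelConstants}}.
#' @param samplesPerPop diploid samples per population (default 40, the
#'   cohort size the analysis is designed around).
#' @return A \code{GenomeConfig}.
#' @export
genomeConfig <- function(sequenceLength = 1e7,
                         recombMap = deskRecombMap(sequenceLength),
                         mutationRate = modelConstants()@mutationRate,
                         samplesPerPop = 40L) {
  new("GenomeConfig",
      sequenceLength = as.numeric(sequenceLength),
      recombMap = recombMap,
      mutationRate = as.numeric(mutationRate),
      samplesPerPop = as.integer(samplesPerPop))
}

#' Phased biallelic haplotype panel
#'
#' Sites-by-haplotypes 0/1 matrix with physical (bp) and genetic (cM) site
#' positions and a per-haplotype population label. Haplotypes 2i-1 and 2i
#' (1-based) belong to diploid individual i.
#'
#' @slot haplotypes integer matrix, sites x haplotypes, values 0/1.
#' @slot posBp site physical positions (bp, 0-based), strictly increasing.
#' @slot posCm site genetic positions (cM), non-decreasing.
#' @slot popLabels character vector, one label per haplotype.
#' @export
setClass("HaplotypePanel", representation(
  haplotypes = "matrix",
  posBp = "numeric",
  posCm = "numeric",
  popLabels = "character"
))

setValidity("HaplotypePanel", function(object) {
  h <- object@haplotypes
  if (nrow(h) != length(object@posBp)) return("one bp position per site required")
  if (nrow(h) != length(object@posCm)) return("one cM position per site required")
  if (ncol(h) != length(object@popLabels)) return("one population label per haplotype")
  if (length(object@posBp) > 1L && any(diff(object@posBp) <= 0))
    return("site positions must be strictly increasing")
  if (nrow(h) > 0L) {
    dc <- rowSums(h)
    if (any(dc <= 0L) || any(dc >= ncol(h)))
      return("every site must be segregating in the panel")
    if (!all(h %in% c(0L, 1L))) return("haplotype entries must be 0/1")
  }
  TRUE
})

#' Set of IBD or ROH segments
#'
#' A thin container over a segment table. For IBD the table has columns
#' \code{id1,id2,startBp,endBp,startCm,endCm,cm,nSnps,score}; for ROH it has
#' \code{id,startBp,endBp,nSnps,lengthKb}. Physical coordinates are 0-based
#' half-open.
#'
#' @slot segments data.frame of segments.
#' @slot kind "IBD" or "ROH".
#' @export
setClass("SegmentSet", representation(segments = "data.frame", kind = "character"))

setValidity("SegmentSet", function(object) {
  if (!object@kind %in% c("IBD", "ROH")) return("kind must be IBD or ROH")
  tb <- object@segments
  if (nrow(tb) == 0L) return(TRUE)
  if (any(tb$endBp <= tb$startBp)) return("segment end must exceed start")
  if (object@kind == "IBD" && any(tb$cm < 0)) return("cM spans must be >= 0")
  TRUE
})

segmentSet <- function(segments, kind) new("SegmentSet", segments = segments, kind = kind)

emptyIbdSegments <- function() {
  data.frame(id1 = integer(), id2 = integer(), startBp = numeric(), endBp = numeric(),
             startCm = numeric(), endCm = numeric(), cm = numeric(),
             nSnps = integer(), score = numeric())
}

emptyRohSegments <- function() {
  data.frame(id = integer(), startBp = numeric(), endBp = numeric(),
             nSnps = integer(), lengthKb = numeric())
}

#' ABC reference table: parameters x summary statistics over simulations
#'
#' @slot params numeric matrix, one row per simulation, columns
#'   \code{paramNames()}.
#' @slot stats numeric matrix, one row per simulation, one column per
#'   registry statistic (46 by default).
#' @slot provenance list recording seeds, configuration hash and registry
#'   version.
#' @export
setClass("ReferenceTable", representation(
  params = "matrix", stats = "matrix", provenance = "list"
))

setValidity("ReferenceTable", function(object) {
  if (nrow(object@params) != nrow(object@stats))
    return("params and stats must have the same number of rows")
  if (!identical(colnames(object@params), paramNames()))
    return("parameter columns must be the five model parameters in order")
  if (anyNA(object@params)) return("parameter values must not be missing")
  TRUE
})

#' Posterior estimate for the five model parameters
#'
#' @slot samples adjusted posterior draws on the natural scale (rows) per
#'   parameter (columns).
#' @slot weights Epanechnikov distance weights, normalised to sum to one.
#' @slot summary data.frame with per-parameter weighted median and 2.5/97.5
#'   weighted percentiles.
#' @slot yearsBP the split-generation summary converted to years BP.
#' @slot method,tolerance the ABC settings used.
#' @export
setClass("PosteriorResult", representation(
  samples = "matrix",
  weights = "numeric",
  summary = "data.frame",
  yearsBP = "numeric",
  method = "character",
  tolerance = "numeric"
))

setValidity("PosteriorResult", function(object) {
  s <- object@summary
  if (!all(c("parameter", "median", "q2.5", "q97.5") %in% names(s)))
    return("summary must have parameter/median/q2.5/q97.5")
  if (any(s$median < s$q2.5 - 1e-9) || any(s$median > s$q97.5 + 1e-9))
    return("median must lie inside the percentile interval")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  TRUE
})

#' ABC configuration
#'
#' @slot tolerance accepted fraction of simulations (default 0.10).
#' @slot method "neuralnet", "loclinear" or "rejection".
#' @slot hiddenUnits hidden-layer size of the neural-net adjustment
#'   (default 4).
#' @slot restarts number of re-seeded neural-net fits averaged per parameter.
#' @slot decay weight-decay regularisation of the neural-net fits.
#' @slot seed integer seed for the adjustment fits.
#' @export
setClass("ABCConfig", representation(
  tolerance = "numeric", method = "character", hiddenUnits = "integer",
  restarts = "integer", decay = "numeric", seed = "integer"
))

setValidity("ABCConfig", function(object) {
  if (object@tolerance <= 0 || object@tolerance > 1) return("tolerance must be in (0, 1]")
  if (!object@method %in% c("neuralnet", "loclinear", "rejection"))
    return("method must be neuralnet, loclinear or rejection")
  if (object@hiddenUnits < 1L) return("hiddenUnits must be >= 1")
  if (object@restarts < 1L) return("restarts must be >= 1")
  if (object@decay < 0) return("decay must be >= 0")
  TRUE
})

#' Construct an ABC configuration
#'
#' Defaults: neural-net regression adjustment with 4
#' hidden neurons at a 10\% tolerance, averaged over 10 re-seeded fits. The
#' weight decay defaults to 1, sized for desk-scale accepted sets (order
#' 10^2 rows against 46 standardised predictors, which weaker decay would
#' interpolate, collapsing the posterior spread); large-scale runs with
#' thousands of accepted rows can lower it.
#'
#' @param tolerance accepted fraction of simulations.
#' @param method one of \code{"neuralnet"}, \code{"loclinear"},
#'   \code{"rejection"}.
#' @param hiddenUnits hidden-layer size for \code{"neuralnet"}.
#' @param restarts re-seeded fits averaged per parameter.
#' @param decay weight-decay regularisation of each fit.
#' @param seed integer seed.
#' @return An \code{ABCConfig}.
#' @export
abcConfig <- function(tolerance = 0.10, method = "neuralnet", hiddenUnits = 4L,
                      restarts = 10L, decay = 1, seed = 1L) {
  new("ABCConfig", tolerance = as.numeric(tolerance), method = method,
      hiddenUnits = as.integer(hiddenUnits), restarts = as.integer(restarts),
      decay = as.numeric(decay), seed = as.integer(seed))
}

#' Holdout validation report
#'
#' @slot table data.frame with per-parameter MAE, MSE, RMSE of posterior
#'   medians against pseudo-observed truths and the coverage frequency of
#'   the [2.5, 97.5] percentile interval.
#' @slot nHoldout number of pseudo-observed rows evaluated.
#' @export
setClass("ValidationReport", representation(table = "data.frame", nHoldout = "integer"))

setValidity("ValidationReport", function(object) {
  tb <- object@table
  if (!all(c("parameter", "mae", "mse", "rmse", "coverage") %in% names(tb)))
    return("report table must have parameter/mae/mse/rmse/coverage")
  if (any(abs(tb$rmse - sqrt(tb$mse)) > 1e-8 * (1 + tb$rmse)))
    return("rmse must equal sqrt(mse)")
  if (any(tb$coverage < 0 | tb$coverage > 1)) return("coverage must be in [0, 1]")
  TRUE
})
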