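#' @describeIn SplitModelParams-class compact display
#' @param object a \code{SplitModelParams}
#' @export
setMethod("show", "SplitModelParams", function(object) {
  v <- paramsToVector(object)
  cat("SplitModelParams:",
      sprintf("%s=%.6g", names(v), v), "\n")
})

setMethod("show", "ModelConstants", function(object) {
  cat(sprintf(
    "ModelConstants: N_fixed=%g at generation %g; mu=%g /bp/gen; %g yr/gen\n",
    object@nAncestralFixed, object@genAncestralChange,
    object@mutationRate, object@generationTimeYears))
})

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec for", nrow(object@table), "parameters:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "DemographyTimeline", function(object) {
  cat("DemographyTimeline (backwards in time, generations):\n")
  print(object@events, row.names = FALSE)
})

setMethod("show", "RecombMap", function(object) {
  cat(sprintf("RecombMap: %d knots, %g bp span, %.4g cM total\n",
              length(object@pos), max(object@pos) - min(object@pos),
              max(object@cm) - min(object@cm)))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d segregating sites x %d haplotypes (%s)\n",
              nrow(object@haplotypes), ncol(object@haplotypes),
              paste(sprintf("%s: %d", names(table(object@popLabels)),
                            table(object@popLabels)), collapse = ", ")))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet[%s]: %d segments\n", object@kind, nrow(object@segments)))
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: %d simulations, %d parameters x %d statistics\n",
              nrow(object@params), ncol(object@params), ncol(object@stats)))
})

setMethod("show", "PosteriorResult", function(object) {
  cat(sprintf("PosteriorResult (%s, tolerance %.3g, %d accepted draws):\n",
              object@method, object@tolerance, nrow(object@samples)))
  print(object@summary, row.names = FALSE)
  cat(sprintf("gen_split in years BP: median %.0f [%.0f, %.0f]\n",
              object@yearsBP[["median"]], object@yearsBP[["q2.5"]],
              object@yearsBP[["q97.5"]]))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport over %d holdouts:\n", object@nHoldout))
  print(object@table, row.names = FALSE)
})

#' Segment table accessor
#' @param x a \code{SegmentSet}
#' @return the underlying segment data.frame
#' @export
segments <- function(x) {
  stopifnot(is(x, "SegmentSet"))
  x@segments
}

#' Number of simulations in a reference table
#' @param x a \code{ReferenceTable}
#' @export
setMethod("nrow", "ReferenceTable", function(x) base::nrow(x@params))

#' Parameter matrix accessor
#' @param x a \code{ReferenceTable}
#' @return numeric matrix of parameter draws
#' @export
refParams <- function(x) {
  stopifnot(is(x, "ReferenceTable"))
  x@params
}

#' Statistic matrix accessor
#' @param x a \code{ReferenceTable}
#' @return numeric matrix of summary statistics
#' @export
refStats <- function(x) {
  stopifnot(is(x, "ReferenceTable"))
  x@stats
}

#' Posterior summary accessor
#' @param x a \code{PosteriorResult}
#' @return data.frame of per-parameter median and percentile bounds
#' @export
posteriorSummary <- function(x) {
  stopifnot(is(x, "PosteriorResult"))
  x@summary
}

#' Posterior draws accessor
#' @param x a \code{PosteriorResult}
#' @return matrix of weighted posterior draws on the natural scale
#' @export
posteriorSamples <- function(x) {
  stopifnot(is(x, "PosteriorResult"))
  x@samples
}

#' Validation table accessor
#' @param x a \code{ValidationReport}
#' @return data.frame of per-parameter errors and coverage
#' @export
validationTable <- function(x) {
  stopifnot(is(x, "ValidationReport"))
  x@table
}
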