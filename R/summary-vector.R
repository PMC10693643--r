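# The fixed, ordered 46-statistic registry. There is no canonical public
# listing of such a set, so the registry reconstructs the statistic
# families (per-population diversity/SFS, IBD length-bin and ROH
# length-class haplotype statistics, cross-population divergence) in a
# data-driven order that can be replaced wholesale via configuration.

registryVersion <- "registry-46-v1"

#' Names of the 46 registry statistics, in order
#'
#' Per population (x2): S, singletons, doubletons, pi, Tajima's D, mean
#' heterozygosity (12). Within-population IBD count and total cM in three
#' cM bins (x2 populations: 12). Within-population ROH count and total kb
#' in classes < 1 Mb and >= 1 Mb (x2: 8). Cross-population: Hudson FST,
#' Dxy, shared, private-A, private-B, fixed differences (6).
#' Between-population IBD count and total cM in three bins (6). Overall S
#' and overall Tajima's D (2).
#'
#' @param pops the two population tags used in the names.
#' @return Character vector of length 46.
#' @export
summaryStatNames <- function(pops = c("cab", "moz")) {
  div <- function(p) paste0(c("S_", "singletons_", "doubletons_", "pi_",
                              "tajd_", "het_"), p)
  ibd <- function(tag) as.vector(t(outer(c("2_4", "4_8", "8_inf"),
                                         c("n", "cm"),
                                         function(b, w) paste0("ibd_", w, "_", b, "_", tag))))
  roh <- function(p) paste0("roh_", c("n_lt1mb_", "kb_lt1mb_", "n_ge1mb_", "kb_ge1mb_"), p)
  c(div(pops[1]), div(pops[2]),
    ibd(pops[1]), ibd(pops[2]),
    roh(pops[1]), roh(pops[2]),
    "fst", "dxy", "shared", paste0("private_", pops[1]),
    paste0("private_", pops[2]), "fixed_diff",
    ibd("between"),
    "S_all", "tajd_all")
}

#' Compute the ordered 46-statistic summary vector
#'
#' The ABC summary function: computes the full registry from a
#' two-population genotype panel, including the IBD (detect, gap-merge,
#' density-filter, bin) and ROH scans. Non-finite values (e.g. FST on a
#' panel with zero between-population diversity) are replaced by 0 with a
#' warning, so downstream distance computations stay defined.
#'
#' @param x a \code{HaplotypePanel}, or a list with elements
#'   \code{genotypes} (sites x individuals), \code{posBp}, \code{labels}.
#' @param map a \code{RecombMap} (used for genetic positions); defaults to
#'   the panel's own cM positions when \code{x} is a panel.
#' @param config optional list overriding scan settings: \code{ibdMinCm},
#'   \code{ibdLod}, \code{mafMin}, \code{errRate}, \code{mergeGapCm},
#'   \code{mergeMaxDiscordant}, \code{minSnpsPerCm}, \code{binsCm}.
#' @return Named numeric vector of length 46 with attribute
#'   \code{registry}.
#' @export
computeSummaryVector <- function(x, map = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    ibdMinCm = 2.0, ibdLod = 3.0, mafMin = 0.01, errRate = 0.001,
    mergeGapCm = 0.6, mergeMaxDiscordant = 1L, minSnpsPerCm = 50,
    binsCm = list(c(2, 4), c(4, 8), c(8, Inf))
  ), config)
  if (is(x, "HaplotypePanel")) {
    g <- panelToGenotypes(x)
    posBp <- x@posBp
    labels <- individualLabels(x)
    cmPos <- if (is.null(map)) x@posCm else mapCM(map, posBp)
  } else {
    g <- x$genotypes; posBp <- x$posBp; labels <- x$labels
    if (is.null(map)) stop("config error: a recombination map is required")
    cmPos <- mapCM(map, posBp)
  }
  pops <- unique(labels)
  if (length(pops) != 2L)
    stop("config error: exactly two labelled populations required, got ",
         length(pops))
  nm <- summaryStatNames(tolower(pops))
  gA <- g[, labels == pops[1], drop = FALSE]
  gB <- g[, labels == pops[2], drop = FALSE]

  dA <- diversityStats(gA)
  dB <- diversityStats(gB)
  dAll <- diversityStats(g)
  dv <- divergenceStats(g, labels, pops[1], pops[2])

  ibdRows <- function(binTable, ga, gb) {
    sel <- (binTable$groupA == ga & binTable$groupB == gb) |
      (binTable$groupA == gb & binTable$groupB == ga)
    d <- binTable[sel, , drop = FALSE]
    d <- d[order(d$binLow), , drop = FALSE]
    as.vector(t(d[, c("count", "totalCm")]))
  }
  if (nrow(g) > 0L && ncol(g) >= 2L) {
    ibd <- detectIBD(g, posBp, cmPos, minCm = cfg$ibdMinCm,
                     lodThreshold = cfg$ibdLod, mafMin = cfg$mafMin,
                     errRate = cfg$errRate)
    ibd <- mergeIBDGaps(ibd, g, posBp, maxGapCm = cfg$mergeGapCm,
                        maxDiscordant = cfg$mergeMaxDiscordant)
    ibd <- filterLowDensity(ibd, posBp, minSnpsPerCm = cfg$minSnpsPerCm)
    bins <- ibdBinStats(ibd, labels, binsCm = cfg$binsCm)
    ibdA <- ibdRows(bins, pops[1], pops[1])
    ibdB <- ibdRows(bins, pops[2], pops[2])
    ibdX <- ibdRows(bins, pops[1], pops[2])
  } else {
    ibdA <- ibdB <- ibdX <- rep(0, 6)
  }

  rohVals <- function(gp) {
    if (nrow(gp) == 0L) return(rep(0, 4))
    segs <- detectROH(gp, posBp, mafMin = cfg$mafMin)
    cls <- rohClassStats(segs, rep("g", ncol(gp)))
    short <- cls[cls$class == "lt1000kb", ]
    long <- cls[cls$class == "ge1000kb", ]
    c(short$count, short$totalKb, long$count, long$totalKb)
  }

  vals <- c(
    dA$S, dA$singletons, dA$doubletons, dA$pi, dA$tajd, dA$het,
    dB$S, dB$singletons, dB$doubletons, dB$pi, dB$tajd, dB$het,
    ibdA, ibdB,
    rohVals(gA), rohVals(gB),
    dv$fst, dv$dxy, dv$shared, dv$privateA, dv$privateB, dv$fixed,
    ibdX,
    dAll$S, dAll$tajd
  )
  names(vals) <- nm
  bad <- !is.finite(vals)
  if (any(bad)) {
    warning("non-finite summary statistics replaced by 0: ",
            paste(nm[bad], collapse = ", "))
    vals[bad] <- 0
  }
  attr(vals, "registry") <- registryVersion
  vals
}
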