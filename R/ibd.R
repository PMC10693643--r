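#' Detect IBD segments between all individual pairs
#'
#' A likelihood-ratio scan on unphased genotypes: at each site the log10
#' ratio of P(genotype pair | the pair shares one haplotype IBD) to
#' P(genotype pair | unrelated, Hardy-Weinberg) is computed from sample
#' allele frequencies, with a small genotype error rate folded in so that
#' opposite homozygotes (impossible under one-haplotype IBD) score strongly
#' negative but finite. Maximal positive-sum runs per pair with cumulative
#' score >= \code{lodThreshold} and genetic length >= \code{minCm} are
#' reported. Sites are pre-filtered to minor allele frequency >
#' \code{mafMin}.
#'
#' @param genotypes integer matrix, sites x individuals, values 0/1/2/NA.
#' @param posBp site physical positions (bp, 0-based), strictly increasing.
#' @param map a \code{RecombMap} covering the sites (or a numeric vector of
#'   per-site cM positions of the same length as \code{posBp}).
#' @param minCm minimum genetic segment length (default 2 cM).
#' @param lodThreshold minimum cumulative log10 score (default 3).
#' @param mafMin minor-allele-frequency filter, strict (default 0.01).
#' @param errRate genotype error rate used in the emission model.
#' @return A \code{SegmentSet} of kind "IBD". \code{id1}/\code{id2} are
#'   column indices into \code{genotypes}; physical coordinates are 0-based
#'   half-open.
#' @export
detectIBD <- function(genotypes, posBp, map, minCm = 2.0, lodThreshold = 3.0,
                      mafMin = 0.01, errRate = 0.001) {
  checkGenotypeMatrix(genotypes)
  if (ncol(genotypes) < 2L) stop("invalid input: at least 2 individuals required")
  if (nrow(genotypes) != length(posBp))
    stop("invalid input: one position per site required")
  cmAll <- if (is.numeric(map)) {
    if (length(map) != length(posBp)) stop("mapping error: cM vector length mismatch")
    map
  } else mapCM(map, posBp)
  if (anyNA(cmAll)) stop("mapping error: sites absent from map")
  ac <- alleleCounts(genotypes)
  p <- ifelse(ac$nAll > 0, ac$cnt / ac$nAll, 0)
  # mafMin = 0 disables the frequency filter entirely
  keep <- if (mafMin > 0) pmin(p, 1 - p) > mafMin else rep(TRUE, length(p))
  if (!any(keep)) return(segmentSet(emptyIbdSegments(), "IBD"))
  g <- genotypes[keep, , drop = FALSE]
  storage.mode(g) <- "integer"
  raw <- .ibdScanCpp(g, p[keep], cmAll[keep], errRate, lodThreshold, minCm)
  if (nrow(raw) == 0L) return(segmentSet(emptyIbdSegments(), "IBD"))
  bp <- posBp[keep]; cm <- cmAll[keep]
  seg <- data.frame(
    id1 = raw$id1, id2 = raw$id2,
    startBp = bp[raw$startIdx], endBp = bp[raw$endIdx] + 1,
    startCm = cm[raw$startIdx], endCm = cm[raw$endIdx],
    cm = cm[raw$endIdx] - cm[raw$startIdx],
    nSnps = raw$endIdx - raw$startIdx + 1L,
    score = raw$score
  )
  segmentSet(seg, "IBD")
}

#' Merge IBD segments across short, concordant gaps
#'
#' Adjacent same-pair segments are merged when the gap between them is
#' shorter than \code{maxGapCm} (genetic length) and contains at most
#' \code{maxDiscordant} opposite-homozygote sites; merging is applied
#' iteratively until no further merge is possible.
#'
#' @param segments a \code{SegmentSet} of kind "IBD".
#' @param genotypes the genotype matrix the segments were called on.
#' @param posBp site physical positions matching \code{genotypes}.
#' @param maxGapCm gap threshold in cM, strict (default 0.6).
#' @param maxDiscordant maximum opposite-homozygote sites in the gap
#'   (default 1).
#' @return A \code{SegmentSet} with merged segments; scores and SNP counts
#'   of merged segments are sums over the merged parts.
#' @export
mergeIBDGaps <- function(segments, genotypes, posBp, maxGapCm = 0.6,
                         maxDiscordant = 1L) {
  stopifnot(is(segments, "SegmentSet"), segments@kind == "IBD")
  tb <- segments@segments
  if (nrow(tb) < 2L) return(segments)
  checkGenotypeMatrix(genotypes)
  pieces <- split(tb, interaction(tb$id1, tb$id2, drop = TRUE))
  merged <- lapply(pieces, function(d) {
    d <- d[order(d$startBp), , drop = FALSE]
    i1 <- d$id1[1]; i2 <- d$id2[1]
    opp <- (genotypes[, i1] == 0L & genotypes[, i2] == 2L) |
      (genotypes[, i1] == 2L & genotypes[, i2] == 0L)
    opp[is.na(opp)] <- FALSE
    oppPos <- posBp[opp]
    repeat {
      if (nrow(d) < 2L) break
      gapCm <- d$startCm[-1] - d$endCm[-nrow(d)]
      nOpp <- vapply(seq_len(nrow(d) - 1L), function(k) {
        sum(oppPos > d$endBp[k] - 1 & oppPos < d$startBp[k + 1])
      }, numeric(1))
      cand <- which(gapCm < maxGapCm & nOpp <= maxDiscordant)
      if (length(cand) == 0L) break
      k <- cand[1]
      d$endBp[k] <- d$endBp[k + 1]; d$endCm[k] <- d$endCm[k + 1]
      d$cm[k] <- d$endCm[k] - d$startCm[k]
      d$nSnps[k] <- d$nSnps[k] + d$nSnps[k + 1]
      d$score[k] <- d$score[k] + d$score[k + 1]
      d <- d[-(k + 1), , drop = FALSE]
    }
    d
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  segmentSet(out, "IBD")
}

#' Remove IBD segments in regions of low SNP density
#'
#' A segment is retained when its SNP density (sites of \code{posBp} inside
#' the segment per cM of genetic length) is at least
#' \code{minSnpsPerCm}; segments containing no SNPs are always removed.
#'
#' @param segments a \code{SegmentSet} of kind "IBD".
#' @param posBp physical positions of the panel's SNPs.
#' @param minSnpsPerCm density threshold (default 50 SNPs/cM; retained at
#'   exactly the threshold).
#' @return A filtered \code{SegmentSet}.
#' @export
filterLowDensity <- function(segments, posBp, minSnpsPerCm = 50) {
  stopifnot(is(segments, "SegmentSet"), segments@kind == "IBD")
  tb <- segments@segments
  if (nrow(tb) == 0L) return(segments)
  nIn <- vapply(seq_len(nrow(tb)), function(k) {
    sum(posBp >= tb$startBp[k] & posBp < tb$endBp[k])
  }, numeric(1))
  dens <- ifelse(tb$cm > 0, nIn / tb$cm, ifelse(nIn > 0, Inf, 0))
  keep <- nIn > 0 & dens >= minSnpsPerCm
  segmentSet(tb[keep, , drop = FALSE], "IBD")
}

#' Bin IBD segments by genetic length per group pair
#'
#' Each segment is assigned to exactly one left-closed, right-open cM bin;
#' counts and total cM are reported per unordered group pair.
#'
#' @param segments a \code{SegmentSet} of kind "IBD".
#' @param groups population label per individual (indexed by segment
#'   \code{id1}/\code{id2}).
#' @param binsCm list of length-2 numeric bin bounds; default
#'   \code{list(c(2,4), c(4,8), c(8,Inf))}.
#' @return data.frame with \code{groupA}, \code{groupB}, \code{binLow},
#'   \code{binHigh}, \code{count}, \code{totalCm}.
#' @export
ibdBinStats <- function(segments, groups,
                        binsCm = list(c(2, 4), c(4, 8), c(8, Inf))) {
  stopifnot(is(segments, "SegmentSet"), segments@kind == "IBD")
  tb <- segments@segments
  lv <- sort(unique(groups))
  pairs <- expand.grid(a = seq_along(lv), b = seq_along(lv))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(pi) {
    ga <- lv[pairs$a[pi]]; gb <- lv[pairs$b[pi]]
    if (nrow(tb) > 0L) {
      g1 <- groups[tb$id1]; g2 <- groups[tb$id2]
      inPair <- (g1 == ga & g2 == gb) | (g1 == gb & g2 == ga)
    } else inPair <- logical(0)
    do.call(rbind, lapply(binsCm, function(b) {
      inBin <- inPair & tb$cm >= b[1] & tb$cm < b[2]
      data.frame(groupA = ga, groupB = gb, binLow = b[1], binHigh = b[2],
                 count = sum(inBin), totalCm = sum(tb$cm[inBin]))
    }))
  }))
  rownames(out) <- NULL
  out
}
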