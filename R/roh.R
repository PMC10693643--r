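#' Detect runs of homozygosity per individual
#'
#' A sliding-window scan in the style of the standard PLINK procedure:
#' windows of \code{windowSnps} consecutive SNPs are classified homozygous
#' when they contain at most \code{windowHetTol} heterozygous and
#' \code{windowMissTol} missing calls; a SNP is ROH-eligible when the
#' fraction of windows overlapping it that are homozygous is at least
#' \code{windowThreshold}. Maximal runs of eligible non-heterozygous SNPs
#' are reported when they contain at least \code{minSnps} SNPs, span at
#' least \code{minKb} kb (floor of bp/1000 compared against the threshold),
#' have a density of at most \code{minDensityKbPerSnp} kb per SNP, and
#' contain no internal gap larger than \code{maxGapKb} kb. Sites are
#' pre-filtered to minor allele frequency > \code{mafMin} across the
#' supplied individuals.
#'
#' @param genotypes integer matrix, sites x individuals, values 0/1/2/NA.
#' @param posBp site physical positions (bp), strictly increasing.
#' @param minSnps minimum SNPs per run (default 50).
#' @param minKb minimum physical span in kb (default 300).
#' @param minDensityKbPerSnp maximum kb per SNP (default 50).
#' @param maxGapKb maximum internal gap in kb (default 1000).
#' @param windowSnps scanning window size in SNPs (default 50).
#' @param windowThreshold minimum homozygous-window fraction (default 0.05).
#' @param windowHetTol heterozygote tolerance per window (default 1).
#' @param windowMissTol missing-call tolerance per window (default 5).
#' @param mafMin minor-allele-frequency filter, strict (default 0.01; use 0
#'   to disable).
#' @return A \code{SegmentSet} of kind "ROH" with columns \code{id} (column
#'   index), \code{startBp}, \code{endBp} (0-based half-open),
#'   \code{nSnps}, \code{lengthKb}.
#' @export
detectROH <- function(genotypes, posBp,
                      minSnps = 50L, minKb = 300, minDensityKbPerSnp = 50,
                      maxGapKb = 1000, windowSnps = 50L, windowThreshold = 0.05,
                      windowHetTol = 1L, windowMissTol = 5L, mafMin = 0.01) {
  checkGenotypeMatrix(genotypes)
  if (nrow(genotypes) != length(posBp))
    stop("invalid input: one position per site required")
  if (length(posBp) > 1L && any(diff(posBp) <= 0))
    stop("invalid input: unsorted site positions")
  ac <- alleleCounts(genotypes)
  p <- ifelse(ac$nAll > 0, ac$cnt / ac$nAll, 0)
  # mafMin = 0 disables the frequency filter entirely
  keep <- if (mafMin > 0) pmin(p, 1 - p) > mafMin else rep(TRUE, length(p))
  g <- genotypes[keep, , drop = FALSE]
  bp <- posBp[keep]
  M <- nrow(g); W <- as.integer(windowSnps)
  out <- emptyRohSegments()
  if (M >= max(W, 1L)) {
    nWin <- M - W + 1L
    for (ind in seq_len(ncol(g))) {
      v <- g[, ind]
      het <- as.numeric(v == 1L); het[is.na(het)] <- 0
      mis <- as.numeric(is.na(v))
      csHet <- c(0, cumsum(het)); csMis <- c(0, cumsum(mis))
      winHet <- csHet[(W + 1):(M + 1)] - csHet[1:nWin]
      winMis <- csMis[(W + 1):(M + 1)] - csMis[1:nWin]
      homWin <- as.numeric(winHet <= windowHetTol & winMis <= windowMissTol)
      # windows covering SNP i: max(1, i-W+1) .. min(i, nWin)
      csHom <- c(0, cumsum(homWin))
      i <- seq_len(M)
      lo <- pmax(1L, i - W + 1L); hi <- pmin(i, nWin)
      nCov <- pmax(hi - lo + 1L, 0L)
      nHom <- ifelse(nCov > 0, csHom[hi + 1L] - csHom[lo], 0)
      eligible <- nCov > 0 & nHom / pmax(nCov, 1L) >= windowThreshold
      isHet <- !is.na(v) & v == 1L
      cand <- eligible & !isHet
      runs <- rle(cand)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        idx <- starts[r]:ends[r]
        # split at physical gaps larger than maxGapKb
        gaps <- which(diff(bp[idx]) > maxGapKb * 1000)
        blockStart <- c(idx[1], idx[gaps + 1])
        blockEnd <- c(idx[gaps], idx[length(idx)])
        for (b in seq_along(blockStart)) {
          sIdx <- blockStart[b]; eIdx <- blockEnd[b]
          nS <- eIdx - sIdx + 1L
          spanBp <- bp[eIdx] - bp[sIdx] + 1
          if (nS >= minSnps &&
              floor(spanBp / 1000) >= minKb &&
              spanBp / 1000 / nS <= minDensityKbPerSnp) {
            out <- rbind(out, data.frame(
              id = ind, startBp = bp[sIdx], endBp = bp[eIdx] + 1,
              nSnps = nS, lengthKb = spanBp / 1000))
          }
        }
      }
    }
  }
  rownames(out) <- NULL
  segmentSet(out, "ROH")
}

#' ROH count and total length per individual group, by length class
#'
#' @param segments a \code{SegmentSet} of kind "ROH".
#' @param groups population label per individual (indexed by \code{id}).
#' @param breakKb class boundary in kb (default 1000: classes < 1 Mb and
#'   >= 1 Mb).
#' @return data.frame with \code{group}, \code{class}, \code{count},
#'   \code{totalKb}.
#' @export
rohClassStats <- function(segments, groups, breakKb = 1000) {
  stopifnot(is(segments, "SegmentSet"), segments@kind == "ROH")
  tb <- segments@segments
  lv <- sort(unique(groups))
  out <- do.call(rbind, lapply(lv, function(g) {
    inG <- if (nrow(tb) > 0L) groups[tb$id] == g else logical(0)
    short <- inG & tb$lengthKb < breakKb
    long <- inG & tb$lengthKb >= breakKb
    data.frame(group = g, class = c(sprintf("lt%gkb", breakKb), sprintf("ge%gkb", breakKb)),
               count = c(sum(short), sum(long)),
               totalKb = c(sum(tb$lengthKb[short]), sum(tb$lengthKb[long])))
  }))
  rownames(out) <- NULL
  out
}
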