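# Standalone cohort statistics: shared f2 alleles and the one-tailed
# permutation test on mean pairwise IBD sharing.

#' Find f2 sites (dataset-wide doubletons)
#'
#' Sites where the total minor-allele count across the full dataset equals
#' exactly 2, outside any masked interval (0-based half-open, e.g.
#' low-complexity or segmental-duplication regions).
#'
#' @param genotypes integer matrix, sites x individuals (all groups).
#' @param posBp site physical positions.
#' @param mask optional data.frame of excluded intervals with columns
#'   \code{start}, \code{end}.
#' @return Integer vector of f2 site indices.
#' @export
findF2Sites <- function(genotypes, posBp, mask = NULL) {
  checkGenotypeMatrix(genotypes)
  ac <- alleleCounts(genotypes)
  minor <- pmin(ac$cnt, ac$nAll - ac$cnt)
  idx <- which(minor == 2)
  if (!is.null(mask) && nrow(mask) > 0L && length(idx) > 0L) {
    masked <- vapply(posBp[idx], function(p)
      any(p >= mask$start & p < mask$end), logical(1))
    idx <- idx[!masked]
  }
  idx
}

#' Group-by-group shared f2 allele matrix
#'
#' For each f2 site carried by two distinct individuals i and j, the cell
#' (group(i), group(j)) is incremented symmetrically; a homozygous
#' doubleton carried twice by one individual is tallied separately as a
#' within-individual count, not in the matrix.
#'
#' @param sites f2 site indices from \code{\link{findF2Sites}}.
#' @param genotypes integer matrix, sites x individuals.
#' @param groups group label per individual.
#' @return List with \code{matrix} (symmetric group x group counts),
#'   \code{withinIndividual} (homozygous-doubleton count), and
#'   \code{totalF2} (= number of sites tallied).
#' @export
f2Sharing <- function(sites, genotypes, groups) {
  lv <- sort(unique(groups))
  M <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  withinInd <- 0L
  for (s in sites) {
    g <- genotypes[s, ]
    cnt <- sum(g, na.rm = TRUE)
    nAll <- 2 * sum(!is.na(g))
    minorDosage <- if (cnt <= nAll - cnt) g else 2L - g
    carriers <- which(!is.na(minorDosage) & minorDosage > 0L)
    if (length(carriers) == 1L) {
      withinInd <- withinInd + 1L  # homozygous doubleton in one individual
    } else if (length(carriers) == 2L) {
      ga <- groups[carriers[1]]; gb <- groups[carriers[2]]
      M[ga, gb] <- M[ga, gb] + 1
      if (ga != gb) M[gb, ga] <- M[gb, ga] + 1
    }
  }
  list(matrix = M, withinIndividual = withinInd, totalF2 = length(sites))
}

# Per-individual-pair total IBD cM within a cM bin, as a symmetric matrix;
# the workhorse behind the group means and the permutation test.
pairIbdMatrix <- function(segments, nInd, binCm = c(2, 4)) {
  stopifnot(is(segments, "SegmentSet"), segments@kind == "IBD")
  tb <- segments@segments
  P <- matrix(0, nInd, nInd)
  if (nrow(tb) > 0L) {
    sel <- tb$cm >= binCm[1] & tb$cm < binCm[2]
    tb <- tb[sel, , drop = FALSE]
    for (k in seq_len(nrow(tb))) {
      P[tb$id1[k], tb$id2[k]] <- P[tb$id1[k], tb$id2[k]] + tb$cm[k]
      P[tb$id2[k], tb$id1[k]] <- P[tb$id2[k], tb$id1[k]] + tb$cm[k]
    }
  }
  P
}

meanPairFromMatrix <- function(P, idxA, idxB) {
  if (identical(sort(idxA), sort(idxB))) {
    if (length(idxA) < 2L)
      stop("invalid input: within-group mean needs at least 2 members")
    sub <- P[idxA, idxA, drop = FALSE]
    sum(sub[upper.tri(sub)]) / (length(idxA) * (length(idxA) - 1) / 2)
  } else {
    if (length(idxA) < 1L || length(idxB) < 1L)
      stop("invalid input: empty group")
    mean(P[idxA, idxB, drop = FALSE])
  }
}

#' Mean pairwise IBD sharing between (or within) groups
#'
#' Total segment cM per pair within the cM bin, averaged over all pairs
#' (a in A, b in B); for A = B, unordered within-group pairs.
#'
#' @param segments a \code{SegmentSet} of kind "IBD".
#' @param groups group label per individual.
#' @param groupA,groupB group labels (equal for a within-group mean).
#' @param binCm cM length bin, left-closed right-open (default c(2, 4)).
#' @return Mean cumulative cM per pair.
#' @export
meanPairwiseIBD <- function(segments, groups, groupA, groupB = groupA,
                            binCm = c(2, 4)) {
  P <- pairIbdMatrix(segments, length(groups), binCm)
  meanPairFromMatrix(P, which(groups == groupA), which(groups == groupB))
}

#' One-tailed permutation test on mean pairwise IBD sharing
#'
#' Tests whether the mean pairwise IBD involving group X exceeds that
#' involving group Y. Two designs are supported: \code{type = "within"}
#' compares within-group means (statistic: mean within-X minus mean
#' within-Y), and \code{type = "between"} compares sharing with a fixed
#' reference group R (statistic: mean R-X minus mean R-Y). Individual
#' labels of X and Y members are permuted \code{nPerm} times;
#' p = (1 + #\{T_perm >= T_obs\}) / (1 + nPerm).
#'
#' @param segments a \code{SegmentSet} of kind "IBD".
#' @param groups group label per individual.
#' @param groupX,groupY the two groups whose labels are exchanged.
#' @param type \code{"within"} or \code{"between"}.
#' @param reference reference group label (required for
#'   \code{type = "between"}).
#' @param binCm cM length bin (default c(2, 4)).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return List with \code{p}, \code{observed}, \code{nPerm}.
#' @export
permutationTestIBD <- function(segments, groups, groupX, groupY,
                               type = c("within", "between"), reference = NULL,
                               binCm = c(2, 4), nPerm = 10000L, seed = 1L) {
  type <- match.arg(type)
  idxX <- which(groups == groupX); idxY <- which(groups == groupY)
  if (length(idxX) < 2L || length(idxY) < 2L)
    stop("invalid input: both groups need at least 2 members")
  if (type == "between") {
    if (is.null(reference)) stop("invalid input: reference group required")
    idxR <- which(groups == reference)
    if (length(idxR) < 1L) stop("invalid input: empty reference group")
  }
  P <- pairIbdMatrix(segments, length(groups), binCm)
  statFun <- if (type == "within") {
    function(ix, iy) meanPairFromMatrix(P, ix, ix) - meanPairFromMatrix(P, iy, iy)
  } else {
    function(ix, iy) meanPairFromMatrix(P, idxR, ix) - meanPairFromMatrix(P, idxR, iy)
  }
  obs <- statFun(idxX, idxY)
  pool <- c(idxX, idxY)
  nX <- length(idxX)
  exceed <- withSeed(seed, {
    count <- 0L
    for (b in seq_len(nPerm)) {
      perm <- sample(pool)
      if (statFun(perm[seq_len(nX)], perm[-seq_len(nX)]) >= obs)
        count <- count + 1L
    }
    count
  })
  list(p = (1 + exceed) / (1 + nPerm), observed = obs, nPerm = as.integer(nPerm))
}
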