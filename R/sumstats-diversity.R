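# Within- and between-population site statistics, computed from derived
# allele dosages. All pairwise-difference quantities are totals per sequence
# pair (summed over sites), matching the brute-force definition of averaging
# Hamming distances over haplotype pairs.

tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from S, pi and the haplotype count
#'
#' @param S number of segregating sites.
#' @param pi mean pairwise differences (per sequence pair, summed over sites).
#' @param n number of haplotypes (>= 2).
#' @return Tajima's D, or NA when undefined (S = 0 or n < 2).
#' @export
tajimasD <- function(S, pi, n) {
  if (n < 2 || S <= 0) return(NA_real_)
  k <- tajimaConstants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# Allele counts per site for a genotype sub-matrix: derived count and total
# called haplotypes.
alleleCounts <- function(g) {
  cnt <- rowSums(g, na.rm = TRUE)
  nAll <- 2 * rowSums(!is.na(g))
  list(cnt = cnt, nAll = nAll)
}

#' Within-population diversity statistics
#'
#' Computes, for one population: the number of segregating sites S,
#' singleton and doubleton counts (derived allele count 1 and 2),
#' nucleotide diversity pi (mean pairwise differences per sequence pair,
#' via the unbiased genotype analogue 2c(n-c)/(n(n-1)) summed over sites),
#' Tajima's D, and the mean observed heterozygosity (fraction of
#' heterozygous genotype calls across individuals and panel sites).
#'
#' @param genotypes integer matrix, sites x individuals, values 0/1/2/NA.
#' @return Named list with \code{S}, \code{singletons}, \code{doubletons},
#'   \code{pi}, \code{tajd}, \code{het}.
#' @export
diversityStats <- function(genotypes) {
  checkGenotypeMatrix(genotypes)
  if (ncol(genotypes) < 2L)
    stop("invalid input: at least 2 individuals required")
  ac <- alleleCounts(genotypes)
  seg <- ac$cnt > 0 & ac$cnt < ac$nAll
  S <- sum(seg)
  piTot <- sum(ifelse(ac$nAll > 1, 2 * ac$cnt * (ac$nAll - ac$cnt) /
                        (ac$nAll * (ac$nAll - 1)), 0))
  n <- 2L * ncol(genotypes)
  list(
    S = S,
    singletons = sum(ac$cnt == 1),
    doubletons = sum(ac$cnt == 2),
    pi = piTot,
    tajd = tajimasD(S, piTot, n),
    het = if (nrow(genotypes) > 0L) mean(genotypes == 1L, na.rm = TRUE) else 0
  )
}

#' Between-population divergence statistics
#'
#' Hudson's FST (1 - Hw/Hb as a ratio of sums over sites, with the unbiased
#' within-population heterozygosity), Dxy (mean between-population pairwise
#' differences per sequence pair, summed over sites), and the exhaustive
#' partition of segregating sites into shared, private-to-A, private-to-B
#' and fixed differences.
#'
#' @param genotypes integer matrix, sites x individuals.
#' @param labels population label per individual (exactly two levels used).
#' @param popA,popB the two population labels; defaults to the first two in
#'   order of appearance.
#' @return Named list with \code{fst}, \code{dxy}, \code{shared},
#'   \code{privateA}, \code{privateB}, \code{fixed}. \code{fst} is NaN when
#'   between-population diversity is zero.
#' @export
divergenceStats <- function(genotypes, labels,
                            popA = unique(labels)[1], popB = unique(labels)[2]) {
  checkGenotypeMatrix(genotypes)
  if (!popA %in% labels || !popB %in% labels)
    stop("invalid input: both populations must be present")
  gA <- genotypes[, labels == popA, drop = FALSE]
  gB <- genotypes[, labels == popB, drop = FALSE]
  a <- alleleCounts(gA); b <- alleleCounts(gB)
  segA <- a$cnt > 0 & a$cnt < a$nAll
  segB <- b$cnt > 0 & b$cnt < b$nAll
  fixed <- (a$cnt == 0 & b$cnt == b$nAll & b$nAll > 0) |
    (a$cnt == a$nAll & a$nAll > 0 & b$cnt == 0)
  ok <- a$nAll > 1 & b$nAll > 1
  hw <- numeric(nrow(genotypes)); hb <- numeric(nrow(genotypes))
  hw[ok] <- 0.5 * (2 * a$cnt[ok] * (a$nAll[ok] - a$cnt[ok]) /
                     (a$nAll[ok] * (a$nAll[ok] - 1)) +
                   2 * b$cnt[ok] * (b$nAll[ok] - b$cnt[ok]) /
                     (b$nAll[ok] * (b$nAll[ok] - 1)))
  hbOk <- a$nAll > 0 & b$nAll > 0
  hb[hbOk] <- (a$cnt[hbOk] * (b$nAll[hbOk] - b$cnt[hbOk]) +
                 b$cnt[hbOk] * (a$nAll[hbOk] - a$cnt[hbOk])) /
    (a$nAll[hbOk] * b$nAll[hbOk])
  list(
    fst = if (sum(hb) > 0) 1 - sum(hw) / sum(hb) else NaN,
    dxy = sum(hb),
    shared = sum(segA & segB),
    privateA = sum(segA & !segB),
    privateB = sum(segB & !segA),
    fixed = sum(fixed)
  )
}
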