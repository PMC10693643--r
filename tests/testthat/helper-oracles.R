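# Brute-force oracles and fixture builders shared across the suite.
# The oracles deliberately use the naive double-loop definitions so they
# stay independent of the package's allele-count implementations.

# Panel from explicit site columns: cols is a list of 0/1 vectors (one per
# site), one entry per haplotype. Returns a sites x haplotypes matrix.
hapMatrix <- function(cols) {
  m <- do.call(rbind, lapply(cols, as.integer))
  storage.mode(m) <- "integer"
  m
}

# Mean pairwise Hamming distance over all haplotype pairs (per sequence
# pair, summed over sites).
bfPi <- function(h) {
  n <- ncol(h)
  if (n < 2) return(0)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(h[, i] != h[, j])
  tot / (n * (n - 1) / 2)
}

bfSegSites <- function(h) {
  dc <- rowSums(h)
  sum(dc > 0 & dc < ncol(h))
}

bfSfsCount <- function(h, k) sum(rowSums(h) == k)

# Hudson FST via per-site pairwise-difference ratios: 1 - sum(Hw)/sum(Hb),
# Hw averaged over the two populations' within-pair differences.
bfHudsonFst <- function(h, hapLabels) {
  pops <- unique(hapLabels)
  stopifnot(length(pops) == 2)
  ia <- which(hapLabels == pops[1]); ib <- which(hapLabels == pops[2])
  hwSum <- 0; hbSum <- 0
  for (s in seq_len(nrow(h))) {
    within <- function(idx) {
      if (length(idx) < 2) return(0)
      tot <- 0; np <- 0
      for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1):length(idx)) {
        tot <- tot + (h[s, idx[i]] != h[s, idx[j]]); np <- np + 1
      }
      tot / np
    }
    between <- mean(outer(h[s, ia], h[s, ib], "!="))
    hwSum <- hwSum + (within(ia) + within(ib)) / 2
    hbSum <- hbSum + between
  }
  if (hbSum == 0) return(NaN)
  1 - hwSum / hbSum
}

bfDxy <- function(h, hapLabels) {
  pops <- unique(hapLabels)
  ia <- which(hapLabels == pops[1]); ib <- which(hapLabels == pops[2])
  tot <- 0
  for (i in ia) for (j in ib) tot <- tot + sum(h[, i] != h[, j])
  tot / (length(ia) * length(ib))
}

# Random segregating panel: sites x nHap, allele frequencies away from the
# boundaries so every site segregates.
randomPanel <- function(nSites, nHap, seed) {
  set.seed(seed)
  h <- matrix(0L, nSites, nHap)
  for (s in seq_len(nSites)) {
    repeat {
      row <- rbinom(nHap, 1, runif(1, 0.1, 0.9))
      if (any(row == 1) && any(row == 0)) break
    }
    h[s, ] <- row
  }
  storage.mode(h) <- "integer"
  h
}

# Genotypes of unrelated individuals drawn from HWE at given frequencies.
hweGenotypes <- function(p, nInd) {
  matrix(rbinom(length(p) * nInd, 2, rep(p, nInd)), nrow = length(p))
}

# f2 sharing by brute-force triple loop over sites x individual pairs.
bfF2Sharing <- function(genotypes, groups, sites) {
  lv <- sort(unique(groups))
  M <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  withinInd <- 0
  for (s in sites) {
    g <- genotypes[s, ]
    cnt <- sum(g); nAll <- 2 * length(g)
    md <- if (cnt <= nAll - cnt) g else 2 - g
    car <- which(md > 0)
    if (length(car) == 1 && md[car] == 2) withinInd <- withinInd + 1
    if (length(car) == 2) {
      a <- groups[car[1]]; b <- groups[car[2]]
      M[a, b] <- M[a, b] + 1
      if (a != b) M[b, a] <- M[b, a] + 1
    }
  }
  list(matrix = M, withinIndividual = withinInd)
}
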