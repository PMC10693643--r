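# IBD and ROH scans on constructed fixtures with hand-enumerable outcomes.

# A pair-focused fixture: nInd unrelated HWE individuals at fixed
# frequencies, with optional genotype overrides for the first two columns.
ibdFixture <- function(nSites = 400, nInd = 8, p = 0.5, seed = 1) {
  set.seed(seed)
  g <- hweGenotypes(rep(p, nSites), nInd)
  storage.mode(g) <- "integer"
  posBp <- seq(0, by = 2500, length.out = nSites)  # 1 Mb, 1 cM/Mb
  list(g = g, posBp = posBp, map = uniformRecombMap(1e-8, 1e6))
}

test_that("an identical genotype pair yields one near-chromosome-length segment", {
  fx <- ibdFixture(seed = 5)
  g <- fx$g
  g[, 2] <- g[, 1]  # duplicate individual
  segs <- segments(detectIBD(g, fx$posBp, fx$map, mafMin = 0, minCm = 0.5))
  s12 <- segs[segs$id1 == 1 & segs$id2 == 2, ]
  expect_identical(nrow(s12), 1L)
  expect_gt(s12$cm, 0.9)  # spans (nearly) the full 1 cM chromosome
  expect_gt(s12$score, 3)
})

test_that("regular opposite homozygotes preclude segments of 2 cM", {
  fx <- ibdFixture(nSites = 1000, seed = 9)
  g <- fx$g
  posBp <- seq(0, by = 10000, length.out = 1000)  # 10 Mb = 10 cM
  map <- uniformRecombMap(1e-8, 1e7)
  # force an opposite-homozygote pair every 10 sites (~0.1 cM)
  idx <- seq(1, 1000, by = 10)
  g[idx, 1] <- 0L; g[idx, 2] <- 2L
  segs <- segments(detectIBD(g, posBp, map, mafMin = 0))
  s12 <- segs[segs$id1 == 1 & segs$id2 == 2, ]
  expect_identical(nrow(s12), 0L)
})

test_that("a shared-haplotype pair carries more IBD than unrelated pairs", {
  wins <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    nSites <- 600
    p <- runif(nSites, 0.05, 0.95)
    shared <- rbinom(nSites, 1, p)       # one haplotype common to ind 1 and 2
    own <- matrix(rbinom(3 * nSites, 1, rep(p, 3)), ncol = 3)
    g <- hweGenotypes(p, 6)
    g[, 1] <- shared + own[, 1]
    g[, 2] <- shared + own[, 2]
    storage.mode(g) <- "integer"
    posBp <- seq(0, by = 5000, length.out = nSites)  # 3 Mb
    segs <- segments(detectIBD(g, posBp, uniformRecombMap(1e-8, 3e6),
                               mafMin = 0, minCm = 1))
    tot <- function(i, j) sum(segs$cm[segs$id1 == i & segs$id2 == j])
    if (tot(1, 2) > tot(3, 4)) wins <- wins + 1L
  }
  expect_gt(wins, 15L)
})

test_that("lowering the LOD threshold never decreases total reported IBD", {
  fx <- ibdFixture(nSites = 800, nInd = 6, seed = 21)
  posBp <- seq(0, by = 5000, length.out = 800)
  map <- uniformRecombMap(1e-8, 4e6)
  tot <- vapply(c(5, 3, 1, 0.5), function(lod) {
    sum(segments(detectIBD(fx$g, posBp, map, lodThreshold = lod,
                           minCm = 0.5, mafMin = 0))$cm)
  }, numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("gap merging follows the <0.6 cM / at-most-one-discordant rule", {
  mkSegs <- function() {
    data.frame(id1 = 1L, id2 = 2L,
               startBp = c(0, 1.5e6), endBp = c(1e6, 2.5e6),
               startCm = c(0, 1.5), endCm = c(1, 2.5),
               cm = c(1, 1), nSnps = c(100L, 100L), score = c(10, 10))
  }
  posBp <- c(1.2e6, 1.3e6)   # two sites inside the 0.5 cM gap
  gOpp0 <- matrix(1L, nrow = 2, ncol = 2)                 # no discordance
  gOpp2 <- matrix(c(0L, 0L, 2L, 2L), nrow = 2)            # two discordant sites
  ss <- splitABC:::segmentSet

  m0 <- segments(mergeIBDGaps(ss(mkSegs(), "IBD"), gOpp0, posBp))
  expect_identical(nrow(m0), 1L)
  expect_equal(m0$cm, 2.5)
  expect_equal(m0$score, 20)

  m2 <- segments(mergeIBDGaps(ss(mkSegs(), "IBD"), gOpp2, posBp))
  expect_identical(nrow(m2), 2L)

  # exactly one discordant homozygote still merges
  gOpp1 <- matrix(c(0L, 1L, 2L, 1L), nrow = 2)
  m1 <- segments(mergeIBDGaps(ss(mkSegs(), "IBD"), gOpp1, posBp))
  expect_identical(nrow(m1), 1L)

  # a 0.7 cM gap does not merge even without discordance
  wide <- mkSegs(); wide$startBp[2] <- 1.7e6; wide$startCm[2] <- 1.7
  mW <- segments(mergeIBDGaps(ss(wide, "IBD"), gOpp0, posBp))
  expect_identical(nrow(mW), 2L)

  # merging iterates to a fixpoint across a chain of segments
  chain <- data.frame(id1 = 1L, id2 = 2L,
                      startBp = c(0, 1.2e6, 2.4e6), endBp = c(1e6, 2.2e6, 3.4e6),
                      startCm = c(0, 1.2, 2.4), endCm = c(1, 2.2, 3.4),
                      cm = c(1, 1, 1), nSnps = c(50L, 50L, 50L),
                      score = c(5, 5, 5))
  mC <- segments(mergeIBDGaps(ss(chain, "IBD"), matrix(1L, 0, 2), numeric(0)))
  expect_identical(nrow(mC), 1L)
  expect_equal(mC$cm, 3.4)
})

test_that("low-density segments are removed with >= retention at the threshold", {
  posBp <- seq(0, 1e6, by = 1000)
  segs <- data.frame(id1 = 1L, id2 = 2L,
                     startBp = c(0, 2e6), endBp = c(1e5, 2.1e6),
                     startCm = c(0, 2), endCm = c(0.1, 2.1),
                     cm = c(0.1, 0.1), nSnps = c(100L, 0L), score = c(5, 5))
  ss <- splitABC:::segmentSet(segs, "IBD")
  # first segment: 100 SNPs in 0.1 cM = 1000/cM, retained; second: 0 SNPs, removed
  kept <- segments(filterLowDensity(ss, posBp, minSnpsPerCm = 50))
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$startBp, 0)
  # exactly at the threshold is retained
  kept2 <- segments(filterLowDensity(ss, posBp, minSnpsPerCm = 1000))
  expect_identical(nrow(kept2), 1L)
  kept3 <- segments(filterLowDensity(ss, posBp, minSnpsPerCm = 1001))
  expect_identical(nrow(kept3), 0L)
})

test_that("IBD length bins are left-closed right-open and conserve totals", {
  segs <- data.frame(id1 = c(1L, 1L, 2L), id2 = c(2L, 3L, 3L),
                     startBp = 0, endBp = 1,
                     startCm = 0, endCm = c(3, 2, 4),
                     cm = c(3, 2, 4), nSnps = 10L, score = 5)
  ss <- splitABC:::segmentSet(segs, "IBD")
  bins <- ibdBinStats(ss, groups = c("A", "A", "B"))
  aa <- bins[bins$groupA == "A" & bins$groupB == "A", ]
  expect_equal(aa$count[aa$binLow == 2], 1)       # the within-A 3 cM segment
  expect_equal(aa$totalCm[aa$binLow == 2], 3)
  ab <- bins[bins$groupA == "A" & bins$groupB == "B", ]
  expect_equal(ab$count[ab$binLow == 2], 1)       # boundary 2 cM falls in [2, 4)
  expect_equal(ab$count[ab$binLow == 4], 1)       # 4 cM falls in [4, 8)
  expect_equal(sum(bins$totalCm), sum(segs$cm))
  expect_equal(sum(bins$count), nrow(segs))
})

test_that("ROH detection reproduces hand-enumerated fixtures", {
  # 60 homozygous SNPs spanning 400 kb: every printed constraint satisfied
  pos <- seq(0, by = 400e3 / 59, length.out = 60)
  g <- matrix(0L, nrow = 60, ncol = 1)
  segs <- segments(detectROH(g, pos, mafMin = 0))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$nSnps, 60L)
  expect_gte(segs$lengthKb, 400)

  # 40 homozygous SNPs spanning 400 kb: fails the 50-SNP minimum
  pos40 <- seq(0, by = 400e3 / 39, length.out = 40)
  expect_identical(nrow(segments(detectROH(matrix(0L, 40, 1), pos40,
                                           mafMin = 0))), 0L)

  # a fully heterozygous individual has no ROH
  gHet <- matrix(1L, nrow = 200, ncol = 1)
  posH <- seq(0, by = 5000, length.out = 200)
  expect_identical(nrow(segments(detectROH(gHet, posH, mafMin = 0))), 0L)

  # a run spanning 400 kb but too sparse (> 50 kb/SNP) is rejected
  posSparse <- seq(0, by = 60e3, length.out = 60)  # 3.5 Mb over 60 SNPs
  expect_identical(nrow(segments(detectROH(matrix(0L, 60, 1), posSparse,
                                           mafMin = 0))), 0L)

  # an internal gap > 1000 kb splits the run; each side fails min_snps
  posGap <- c(seq(0, by = 5000, length.out = 30),
              seq(2e6, by = 5000, length.out = 30))
  expect_identical(nrow(segments(detectROH(matrix(0L, 60, 1), posGap,
                                           mafMin = 0))), 0L)

  # a single heterozygote inside an otherwise qualifying 101-SNP run
  # splits it into two runs that both still qualify via window tolerance
  pos101 <- seq(0, by = 4000, length.out = 101)   # 400 kb
  gMid <- matrix(0L, 101, 1); gMid[51, 1] <- 1L
  out <- segments(detectROH(gMid, pos101, minSnps = 50L, minKb = 100,
                            mafMin = 0))
  expect_identical(nrow(out), 2L)
  expect_identical(out$nSnps, c(50L, 50L))
})

test_that("spanning 400 kb of truly homozygous windows tolerates sporadic missing calls", {
  pos <- seq(0, by = 4000, length.out = 120)
  g <- matrix(0L, 120, 1)
  g[c(20, 60, 100), 1] <- NA   # under the 5-missing window tolerance
  segs <- segments(detectROH(g, pos, mafMin = 0))
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$nSnps, 120L)
})
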