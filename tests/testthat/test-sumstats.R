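test_that("diversity statistics match the brute-force oracle on the worked panel", {
  # 4 haplotypes, three sites with derived patterns 1000, 1100, 1110
  h <- hapMatrix(list(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0)))
  g <- panelToGenotypes(h)
  d <- diversityStats(g)
  expect_identical(d$S, 3L)
  expect_equal(d$pi, bfPi(h))
  expect_equal(d$pi, 10 / 6)
  expect_identical(d$singletons, 1L)
  expect_identical(d$doubletons, 1L)
})

test_that("pi, S, SFS counts and FST match brute force exactly on random panels", {
  for (seed in 1:6) {
    nHap <- sample(c(4, 8), 1)
    h <- randomPanel(nSites = sample(50:200, 1), nHap = nHap, seed = seed)
    g <- panelToGenotypes(h)
    d <- diversityStats(g)
    expect_identical(d$S, bfSegSites(h))
    expect_equal(d$pi, bfPi(h), tolerance = 1e-12)
    expect_identical(d$singletons, as.integer(bfSfsCount(h, 1)))
    expect_identical(d$doubletons, as.integer(bfSfsCount(h, 2)))
    labels <- rep(c("A", "B"), each = nHap / 4)   # per individual
    hapLabels <- rep(labels, each = 2)
    dv <- divergenceStats(g, labels)
    expect_equal(dv$fst, bfHudsonFst(h, hapLabels), tolerance = 1e-12)
    expect_equal(dv$dxy, bfDxy(h, hapLabels), tolerance = 1e-12)
  }
})

test_that("monomorphic panels give zero diversity", {
  g <- matrix(0L, nrow = 5, ncol = 4)
  d <- diversityStats(g)
  expect_identical(d$S, 0L)
  expect_equal(d$pi, 0)
  expect_equal(d$het, 0)
  expect_true(is.na(d$tajd))
})

test_that("Tajima's D is zero when pi equals Watterson's estimator", {
  # with S = a1 (in units where S/a1 = pi), D's numerator vanishes
  n <- 10
  a1 <- sum(1 / (1:(n - 1)))
  S <- 20
  expect_equal(tajimasD(S, S / a1, n), 0)
})

test_that("site classification partitions segregating sites exhaustively", {
  for (seed in 7:10) {
    h <- randomPanel(120, 12, seed = seed)
    g <- panelToGenotypes(h)
    labels <- rep(c("A", "B"), each = 3)
    dv <- divergenceStats(g, labels)
    sTotal <- diversityStats(g)$S
    expect_identical(dv$shared + dv$privateA + dv$privateB + dv$fixed,
                     as.integer(sTotal))
  }
  # a fixed difference is classified and maximally differentiated
  gf <- cbind(matrix(0L, 4, 2), matrix(2L, 4, 2))
  dv <- divergenceStats(gf, c("A", "A", "B", "B"))
  expect_identical(dv$fixed, 4L)
  expect_equal(dv$fst, 1)
  # identical allele frequencies give FST ~ 0 (small negative finite-sample
  # bias of -1/(n-1) from the unbiased within-population heterozygosity)
  hEq <- randomPanel(200, 40, seed = 42)
  gEq <- panelToGenotypes(cbind(hEq, hEq))
  dvEq <- divergenceStats(gEq, rep(c("A", "B"), each = 20))
  expect_lt(abs(dvEq$fst), 0.05)
})

test_that("the summary vector has the fixed 46-entry registry and is invariant to individual order", {
  expect_length(summaryStatNames(), 46L)
  h <- randomPanel(300, 24, seed = 13)
  posBp <- sort(sample(1e6, 300))
  m <- uniformRecombMap(1e-8, 1e6)
  labels <- rep(c("CAB", "MOZ"), each = 6)
  g <- panelToGenotypes(h)
  sv <- computeSummaryVector(list(genotypes = g, posBp = posBp, labels = labels),
                             map = m)
  expect_length(sv, 46L)
  expect_identical(names(sv), summaryStatNames())
  expect_true(all(is.finite(sv)))
  # permute individuals within populations: the vector is unchanged
  permA <- sample(1:6); permB <- 6 + sample(1:6)
  gPerm <- g[, c(permA, permB)]
  svPerm <- computeSummaryVector(
    list(genotypes = gPerm, posBp = posBp, labels = labels), map = m)
  expect_equal(svPerm, sv)
  # identical input gives an identical vector
  sv2 <- computeSummaryVector(list(genotypes = g, posBp = posBp, labels = labels),
                              map = m)
  expect_identical(sv, sv2)
})

test_that("two identical monomorphic populations trigger the NaN policy", {
  g <- matrix(0L, nrow = 3, ncol = 8)
  labels <- rep(c("CAB", "MOZ"), each = 4)
  expect_warning(
    sv <- computeSummaryVector(list(genotypes = g, posBp = c(10, 20, 30),
                                    labels = labels),
                               map = uniformRecombMap(1e-8, 100)),
    "non-finite")
  expect_true(all(is.finite(sv)))
  expect_length(sv, 46L)
})
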