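test_that("f2 site finding keeps exact doubletons outside masked regions", {
  g <- matrix(0L, nrow = 5, ncol = 6)
  g[1, 1] <- 1L                      # singleton: excluded
  g[2, c(1, 4)] <- 1L                # doubleton in two individuals: kept
  g[3, 2] <- 2L                      # homozygous doubleton: kept
  g[4, ] <- 2L; g[4, 5] <- 1L        # minor count 1 on the other allele
  g[5, c(2, 6)] <- 1L                # doubleton inside the mask: excluded
  posBp <- c(100, 200, 300, 400, 500)
  mask <- data.frame(start = 450, end = 550)
  sites <- findF2Sites(g, posBp, mask)
  expect_identical(sites, c(2L, 3L))
  expect_identical(findF2Sites(g, posBp), c(2L, 3L, 5L))
})

test_that("f2 sharing tallies group pairs symmetrically and conserves totals", {
  groups <- c("A", "A", "B", "B", "C", "C")
  g <- matrix(0L, nrow = 4, ncol = 6)
  g[1, c(1, 3)] <- 1L   # A-B sharing
  g[2, c(1, 2)] <- 1L   # within-A sharing
  g[3, 5] <- 2L         # within-individual doubleton (group C)
  g[4, c(4, 6)] <- 1L   # B-C sharing
  sites <- findF2Sites(g, seq_len(4) * 100)
  sh <- f2Sharing(sites, g, groups)
  expect_equal(sh$matrix["A", "B"], 1)
  expect_equal(sh$matrix["B", "A"], 1)
  expect_equal(sh$matrix["A", "A"], 1)
  expect_equal(sh$matrix["B", "C"], 1)
  expect_equal(sh$withinIndividual, 1L)
  expect_true(isSymmetric(sh$matrix))
  # upper triangle + diagonal + within-individual = total f2 sites
  expect_equal(sum(sh$matrix[upper.tri(sh$matrix, diag = TRUE)]) +
                 sh$withinIndividual, sh$totalF2)
})

test_that("f2 sharing equals the brute-force triple loop on random panels", {
  for (seed in 1:4) {
    set.seed(seed)
    nInd <- 20
    g <- matrix(rbinom(300 * nInd, 2, 0.04), nrow = 300)
    storage.mode(g) <- "integer"
    groups <- sample(c("A", "B", "C", "D"), nInd, replace = TRUE)
    while (length(unique(groups)) < 4)
      groups <- sample(c("A", "B", "C", "D"), nInd, replace = TRUE)
    sites <- findF2Sites(g, seq_len(300))
    sh <- f2Sharing(sites, g, groups)
    bf <- bfF2Sharing(g, groups, sites)
    expect_equal(sh$matrix, bf$matrix)
    expect_equal(sh$withinIndividual, bf$withinIndividual,
                 ignore_attr = TRUE)
  }
})

mkIbdSet <- function(df) splitABC:::segmentSet(df, "IBD")

test_that("mean pairwise IBD matches manual enumeration on a 4-individual fixture", {
  segs <- mkIbdSet(data.frame(
    id1 = c(1L, 1L, 3L), id2 = c(2L, 3L, 4L),
    startBp = 0, endBp = 1, startCm = 0, endCm = c(3, 2.5, 3.5),
    cm = c(3, 2.5, 3.5), nSnps = 10L, score = 5))
  groups <- c("X", "X", "Y", "Y")
  # within X: only pair (1,2) -> 3 cM over 1 pair
  expect_equal(meanPairwiseIBD(segs, groups, "X"), 3)
  # within Y: pair (3,4) -> 3.5
  expect_equal(meanPairwiseIBD(segs, groups, "Y"), 3.5)
  # between X and Y: pairs (1,3),(1,4),(2,3),(2,4): only (1,3) has 2.5
  expect_equal(meanPairwiseIBD(segs, groups, "X", "Y"), 2.5 / 4)
  # one segment between the only A-B pair
  segs1 <- mkIbdSet(data.frame(id1 = 1L, id2 = 2L, startBp = 0, endBp = 1,
                               startCm = 0, endCm = 3, cm = 3, nSnps = 5L,
                               score = 4))
  expect_equal(meanPairwiseIBD(segs1, c("A", "B"), "A", "B"), 3)
  # no segments -> mean 0
  empty <- mkIbdSet(splitABC:::emptyIbdSegments())
  expect_equal(meanPairwiseIBD(empty, groups, "X", "Y"), 0)
  expect_error(meanPairwiseIBD(empty, c("X", "Y"), "X"), "at least 2")
})

test_that("maximal separation yields the smallest attainable p-value", {
  # 20 + 20 individuals; IBD only within X
  n <- 40
  groups <- rep(c("X", "Y"), each = 20)
  prs <- t(combn(1:20, 2))
  segs <- mkIbdSet(data.frame(
    id1 = as.integer(prs[, 1]), id2 = as.integer(prs[, 2]),
    startBp = 0, endBp = 1, startCm = 0, endCm = 3, cm = 3,
    nSnps = 5L, score = 4))
  res <- permutationTestIBD(segs, groups, "X", "Y", type = "within",
                            nPerm = 999L, seed = 3)
  expect_equal(res$p, 1 / 1000)
  expect_equal(res$observed, 3)
  # determinism
  res2 <- permutationTestIBD(segs, groups, "X", "Y", type = "within",
                             nPerm = 999L, seed = 3)
  expect_identical(res$p, res2$p)
})

test_that("the between-group design tests sharing with a fixed reference group", {
  groups <- c(rep("R", 4), rep("X", 4), rep("Y", 4))
  df <- expand.grid(id1 = 1:4, id2 = 5:8)
  segs <- mkIbdSet(data.frame(
    id1 = as.integer(df$id1), id2 = as.integer(df$id2),
    startBp = 0, endBp = 1, startCm = 0, endCm = 2.5, cm = 2.5,
    nSnps = 5L, score = 4))
  res <- permutationTestIBD(segs, groups, "X", "Y", type = "between",
                            reference = "R", nPerm = 499L, seed = 5)
  expect_lt(res$p, 0.05)
  expect_equal(res$observed, 2.5)
})

test_that("permutation p-values stay in (0, 1] and increase for reversed direction", {
  set.seed(6)
  n <- 16
  groups <- rep(c("X", "Y"), each = 8)
  prs <- t(combn(seq_len(n), 2))
  segs <- mkIbdSet(data.frame(
    id1 = as.integer(prs[, 1]), id2 = as.integer(prs[, 2]),
    startBp = 0, endBp = 1, startCm = 0, endCm = 2 + runif(nrow(prs)) * 2,
    cm = 2 + runif(nrow(prs)) * 2, nSnps = 5L, score = 4))
  # within-X excess, keeping every segment inside the 2-4 cM bin
  withinX <- groups[segs@segments$id1] == "X" & groups[segs@segments$id2] == "X"
  segs@segments$cm[withinX] <- 3.8
  segs@segments$cm[!withinX] <- 2 + runif(sum(!withinX)) * 0.5
  pXY <- permutationTestIBD(segs, groups, "X", "Y", nPerm = 299L, seed = 7)$p
  pYX <- permutationTestIBD(segs, groups, "Y", "X", nPerm = 299L, seed = 7)$p
  expect_gt(pXY, 0); expect_lte(pXY, 1)
  expect_gt(pYX, 0); expect_lte(pYX, 1)
  expect_lt(pXY, pYX)
})
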