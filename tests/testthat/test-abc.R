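# A small synthetic reference where the statistics are linear in the
# parameters plus noise; informative enough for the adjustment machinery
# and cheap to rebuild.
linearReference <- function(n = 1000, nStats = 8, noise = 0.1, seed = 1) {
  set.seed(seed)
  prior <- defaultPriors()
  params <- as.matrix(samplePrior(prior, n, seed = seed))
  thetaT <- params
  b <- priorBounds(prior)
  for (pn in paramNames())
    thetaT[, pn] <- logitTransform(params[, pn], b$lower[[pn]], b$upper[[pn]])
  W <- matrix(rnorm(5 * nStats), 5, nStats)
  stats <- scale(thetaT) %*% W + matrix(rnorm(n * nStats, sd = noise), n, nStats)
  colnames(stats) <- paste0("stat", seq_len(nStats))
  new("ReferenceTable", params = params, stats = stats,
      provenance = list(prior = prior))
}

test_that("robust standardisation drops constant columns and is idempotent", {
  ref <- matrix(rnorm(500), 100, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  ref[, 3] <- 7
  obs <- c(ref[1, 1:2], 7, ref[1, 4:5])
  expect_warning(std <- standardizeStats(ref, obs), "zero-variance")
  expect_identical(ncol(std$ref), 4L)
  # an observation at the reference median standardises to exactly 0
  refB <- cbind(a = rnorm(50), b = rnorm(50, 2, 0.01))
  stdB <- standardizeStats(refB, c(0.5, median(refB[, "b"])))
  expect_equal(stdB$obs[2], 0, ignore_attr = TRUE)
  # idempotence: re-standardising standardised data changes little
  std2 <- standardizeStats(std$ref, std$obs)
  expect_equal(apply(std2$ref, 2, median), rep(0, 4), ignore_attr = TRUE)
  expect_error(standardizeStats(matrix(1, 10, 2), c(1, 1)), "zero variance")
})

test_that("rejection accepts exactly ceiling(tolerance * n) closest rows", {
  set.seed(2)
  ref <- matrix(rnorm(1000 * 4), 1000, 4)
  obs <- rnorm(4)
  rej <- rejectionSample(ref, obs, 0.1)
  expect_length(rej$accepted, 100L)
  d <- sqrt(colSums((t(ref) - obs)^2))
  expect_equal(sort(rej$distances), sort(d)[1:100])
  expect_true(all(diff(rej$distances) >= 0))
  # tolerance 1 accepts everything
  expect_length(rejectionSample(ref, obs, 1)$accepted, 1000L)
  # a row identical to the observation is accepted at distance 0
  ref[17, ] <- obs
  rej2 <- rejectionSample(ref, obs, 0.05)
  expect_identical(rej2$accepted[1], 17L)
  expect_equal(rej2$distances[1], 0)
  expect_error(rejectionSample(ref[1:5, ], obs, 0.01), "inference error")
})

test_that("logit transform round-trips and honours the algebra", {
  x <- seq(10.001, 99.999, length.out = 50)
  y <- logitTransform(x, 10, 100)
  expect_equal(logitInverse(y, 10, 100), x, tolerance = 1e-9)
  expect_equal(logitTransform(55, 10, 100), 0)
  # x = lower + (upper - lower)/(1 + e) maps to exactly -1
  expect_equal(logitTransform(10 + 90 / (1 + exp(1)), 10, 100), -1)
  # boundaries are nudged inside; any real maps back inside the bounds
  expect_true(is.finite(logitTransform(10, 10, 100)))
  expect_true(all(logitInverse(c(-1e3, 0, 1e3), 10, 100) > 10 - 1e-12))
  expect_true(all(logitInverse(c(-1e3, 0, 1e3), 10, 100) < 100 + 1e-12))
  expect_error(logitTransform(9, 10, 100), "outside")
})

test_that("rejection posterior equals the accepted draws and their raw medians", {
  ref <- linearReference(n = 500, seed = 3)
  obs <- refStats(ref)[7, ]
  post <- estimatePosterior(ref, obs, abcConfig(tolerance = 1, method = "rejection"))
  # tolerance 1 + rejection: the posterior is the prior sample itself
  expect_identical(nrow(posteriorSamples(post)), 500L)
  for (pn in paramNames()) {
    expect_setequal(posteriorSamples(post)[, pn], refParams(ref)[, pn])
    expect_equal(posteriorSummary(post)$median[posteriorSummary(post)$parameter == pn],
                 median(refParams(ref)[, pn]))
  }
  # years-BP reporting multiplies the split-generation summary by 27
  gs <- posteriorSummary(post)[posteriorSummary(post)$parameter == "gen_split", ]
  expect_equal(post@yearsBP[["median"]], gs$median * 27)
})

test_that("posterior support is confined to the prior bounds", {
  ref <- linearReference(n = 600, seed = 4)
  obs <- refStats(ref)[11, ]
  b <- priorBounds(defaultPriors())
  for (method in c("loclinear", "neuralnet")) {
    post <- estimatePosterior(ref, obs,
                              abcConfig(tolerance = 0.2, method = method,
                                        restarts = 2L, seed = 9L))
    s <- posteriorSamples(post)
    for (pn in paramNames()) {
      expect_true(all(s[, pn] >= b$lower[[pn]] & s[, pn] <= b$upper[[pn]]))
    }
    expect_equal(sum(post@weights), 1)
    sm <- posteriorSummary(post)
    expect_true(all(sm$median >= sm$q2.5 & sm$median <= sm$q97.5))
  }
})

test_that("seeded estimation is reproducible", {
  ref <- linearReference(n = 400, seed = 5)
  obs <- refStats(ref)[3, ]
  cfg <- abcConfig(tolerance = 0.25, method = "neuralnet", restarts = 3L,
                   seed = 21L)
  p1 <- estimatePosterior(ref, obs, cfg)
  p2 <- estimatePosterior(ref, obs, cfg)
  expect_identical(posteriorSamples(p1), posteriorSamples(p2))
  expect_identical(posteriorSummary(p1), posteriorSummary(p2))
})

test_that("uninformative statistics leave the accepted marginal unchanged", {
  # statistics independent of the parameters: the adjustment should not
  # distort the accepted-set marginal (no-signal null)
  set.seed(8)
  n <- 800
  prior <- defaultPriors()
  params <- as.matrix(samplePrior(prior, n, seed = 8))
  stats <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("s", 1:6)))
  ref <- new("ReferenceTable", params = params, stats = stats,
             provenance = list(prior = prior))
  obs <- stats[5, ]
  post <- estimatePosterior(ref, obs, abcConfig(tolerance = 0.25,
                                                method = "loclinear"))
  rej <- estimatePosterior(ref, obs, abcConfig(tolerance = 0.25,
                                               method = "rejection"))
  ks <- suppressWarnings(ks.test(log(posteriorSamples(post)[, "n_cab_present"]),
                                 log(posteriorSamples(rej)[, "n_cab_present"])))
  expect_gt(ks$p.value, 0.01)
})

test_that("loclinear adjustment reduces error on a linear testbed", {
  ref <- linearReference(n = 1200, noise = 0.05, seed = 10)
  errs <- sapply(c("rejection", "loclinear"), function(m) {
    tot <- 0
    for (r in c(31, 57, 83)) {
      obs <- refStats(ref)[r, ]
      truth <- refParams(ref)[r, ]
      sub <- new("ReferenceTable", params = refParams(ref)[-r, ],
                 stats = refStats(ref)[-r, ], provenance = ref@provenance)
      post <- estimatePosterior(sub, obs, abcConfig(tolerance = 0.1, method = m))
      s <- posteriorSummary(post); rownames(s) <- s$parameter
      tot <- tot + sum(abs(log(s[paramNames(), "median"]) - log(truth)))
    }
    tot
  })
  expect_lt(errs["loclinear"], errs["rejection"])
})
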