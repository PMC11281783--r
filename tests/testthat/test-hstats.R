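# Hierarchical bootstrap engine and KS-gated classical tests.

test_that("degenerate inputs give degenerate bootstrap distributions", {
  r <- hierarchicalBootstrapMean(list(s1 = 3), nResamples = 200L, seed = 1L)
  expect_equal(unique(bootMeans(r)), 3)
  expect_equal(unname(bootCI(r)), c(3, 3))
  r0 <- hierarchicalBootstrapMean(list(a = rep(0, 5), b = rep(0, 3)),
                                  nResamples = 200L, seed = 1L)
  expect_equal(pValue(r0), 1)   # all-zero data: p("greater") = 1
  expect_error(hierarchicalBootstrapMean(list()), "no sites")
})

test_that("constant positive differences give one-sided p of zero", {
  r <- hierarchicalPairedTest(list(a = rep(1, 10), b = rep(1, 6)),
                              direction = "greater", nResamples = 500L,
                              seed = 2L)
  expect_equal(pValue(r), 0)
  expect_equal(pValue(r, "two.sided"), 0)
})

test_that("sign-flipping the data swaps the two tail proportions", {
  set.seed(3)
  vals <- list(a = rnorm(20, 0.2), b = rnorm(15, 0.2), c = rnorm(25, 0.2))
  r1 <- hierarchicalPairedTest(vals, nResamples = 2000L, seed = 7L)
  r2 <- hierarchicalPairedTest(lapply(vals, function(x) -x),
                               nResamples = 2000L, seed = 7L)
  expect_equal(r1@pLow, r2@pHigh)
  expect_equal(r1@pHigh, r2@pLow)
})

test_that("resampling preserves site and per-site value counts", {
  # sites with distinct constant values: every achievable replicate mean is
  # a count-preserving combination (2 values from the first drawn site's
  # count, etc.); unequal site sizes exercise the general path
  vals <- list(a = c(0, 0), b = 3)
  r <- hierarchicalBootstrapMean(vals, nResamples = 500L, seed = 4L)
  expect_true(all(bootMeans(r) %in% c(0, 1, 3)))
  # equal sizes use the vectorized path; only {0, 1.5, 3} are achievable
  vals2 <- list(a = c(0, 0), b = c(3, 3))
  r2 <- hierarchicalBootstrapMean(vals2, nResamples = 500L, seed = 4L)
  expect_true(all(bootMeans(r2) %in% c(0, 1.5, 3)))
})

test_that("a single site reduces to the flat bootstrap of its values", {
  set.seed(5)
  x <- rnorm(40)
  r <- hierarchicalBootstrapMean(list(only = x), nResamples = 4000L,
                                 seed = 6L)
  flat <- replicate(4000, mean(sample(x, length(x), replace = TRUE)))
  ks <- suppressWarnings(ks.test(bootMeans(r), flat)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("bootstrap mean converges to the pooled grand mean", {
  # with equal site sizes the replicate-mean expectation is the pooled
  # grand mean (= mean of site means); Monte-Carlo tolerance at 2e4 reps
  vals <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(-4, 0, 2))
  r <- hierarchicalBootstrapMean(vals, nResamples = 20000L, seed = 8L)
  sem <- sd(bootMeans(r)) / sqrt(r@nResamples)
  expect_lt(abs(mean(bootMeans(r)) - mean(unlist(vals))), 5 * sem)
})

test_that("unpaired comparisons order, swap, and calibrate correctly", {
  rAB <- hierarchicalUnpairedTest(list(a = rep(1, 8)), list(b = rep(0, 8)),
                                  direction = "greater",
                                  nResamples = 500L, seed = 9L)
  expect_equal(pValue(rAB), 0)
  expect_equal(rAB@estimate, 1)
  set.seed(10)
  A <- list(s1 = rnorm(30), s2 = rnorm(30))
  B <- list(s1 = rnorm(30), s2 = rnorm(30))
  r1 <- hierarchicalUnpairedTest(A, B, nResamples = 3000L, seed = 11L)
  r2 <- hierarchicalUnpairedTest(B, A, nResamples = 3000L, seed = 11L)
  expect_lt(abs(r1@pLow - r2@pHigh), 0.05)
  # over repeated equal-distribution datasets the one-sided p averages 0.5
  ps <- vapply(1:40, function(i) {
    set.seed(2000 + i)
    pValue(hierarchicalUnpairedTest(list(s = rnorm(25)), list(s = rnorm(25)),
                                    nResamples = 300L, seed = 3000L + i))
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("binwise trace comparison flags shifted bins and respects the null", {
  set.seed(12)
  nU <- 40; nT <- 30
  sites <- rep(c("a", "b"), each = nU / 2)
  A <- matrix(rnorm(nU * nT, 0, 0.05), nU)
  outNull <- binwiseTraceComparison(A, A + matrix(rnorm(nU * nT, 0, 0.05),
                                                  nU),
                                    sites, nResamples = 400L, seed = 13L)
  expect_lt(mean(outNull$significant), 0.15)
  outShift <- binwiseTraceComparison(A + 1, A, sites, nResamples = 400L,
                                     seed = 13L)
  expect_true(all(outShift$significant))
  expect_equal(outShift$correction, "none")
  outRep <- binwiseTraceComparison(A + 1, A, sites, nResamples = 400L,
                                   seed = 13L)
  expect_identical(outShift$p, outRep$p)
})

test_that("the KS gate routes to parametric or rank tests as appropriate", {
  set.seed(14)
  skewed <- rlnorm(40, 0, 1.5)
  out <- classicalSiteTest(skewed, skewed * 0.5 + rlnorm(40, 0, 1.5),
                           paired = TRUE)
  expect_false(out$normal)
  expect_match(out$test, "Wilcoxon")
  # near-normal data mostly pass the gate
  branch <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    classicalSiteTest(rnorm(30), rnorm(30, 0.2))$normal
  }, logical(1))
  expect_gte(mean(branch), 0.9)
  # identical paired samples: p = 1 regardless of branch
  x <- rnorm(20)
  expect_equal(classicalSiteTest(x, x, paired = TRUE)$p.value, 1)
})
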