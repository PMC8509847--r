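test_that("exhaustive sign test enumerates all 2^n assignments exactly", {
  # n = 12, all diffs +1: only the all-positive assignment reaches D' >= 1
  res <- signPermutationTest(rep(0, 12), rep(1, 12))
  expect_true(res@exhaustive)
  expect_equal(res@nRealizations, 4096)
  expect_equal(res@p, 1 / 4096)
  expect_equal(round(res@p, 7), 0.0002441)
  # all diffs zero
  expect_equal(signPermutationTest(rep(1, 5), rep(1, 5))@p, 1)
  # n = 3, diffs {3, 2, 1}: only (+,+,+) has D' >= 2
  res3 <- signPermutationTest(c(3, 2, 1))
  expect_equal(res3@p, 1 / 8)
  expect_equal(res3@observedD, 2)
  # negative direction mirrors the positive one
  resn <- signPermutationTest(-c(3, 2, 1))
  expect_equal(resn@p, 1 / 8)
})

test_that("exhaustive p-values agree with an independent enumeration oracle", {
  set.seed(20)
  for (r in 1:25) {
    d <- rnorm(sample(4:10, 1), mean = 0.4)
    expect_equal(signPermutationTest(d)@p, bfSignPermP(d), tolerance = 1e-12)
  }
})

test_that("exhaustive p-values at n = 12 are multiples of 2^-12", {
  set.seed(21)
  for (r in 1:20) {
    d <- rnorm(12, 0.3, 1)
    p <- signPermutationTest(d)@p
    expect_lt(abs(p * 4096 - round(p * 4096)), 1e-9)
    expect_gte(p, 2^-12)
  }
})

test_that("the realization budget always triggers exact enumeration at n = 12", {
  set.seed(22)
  d <- rnorm(12, 0.4, 1)
  res <- signPermutationTest(d, nRealizations = 1e6)
  expect_true(res@exhaustive)       # 2^12 = 4096 <= 1e6
  expect_equal(res@nRealizations, 4096)
})

test_that("sampled p-values agree with exhaustive ones within Monte-Carlo error", {
  # force the sampling path with a budget below 2^12 and compare against
  # the exact enumeration of the same differences
  set.seed(23)
  nr <- 2000
  for (r in 1:50) {
    d <- rnorm(12, runif(1, 0, 0.5), 1)
    pex <- signPermutationTest(d)@p
    ps <- signPermutationTest(d, nRealizations = nr, seed = 100 + r)
    expect_false(ps@exhaustive)
    se <- sqrt(pex * (1 - pex) / nr)
    expect_lt(abs(ps@p - pex), 3 * se + 2 / nr)
  }
})

test_that("sampling mode is seeded and reproducible", {
  set.seed(24)
  d <- rnorm(21, 0.45, 1)            # 2^21 > 1e5 forces sampling
  r1 <- signPermutationTest(d, nRealizations = 1e5, seed = 7)
  r2 <- signPermutationTest(d, nRealizations = 1e5, seed = 7)
  expect_false(r1@exhaustive)
  expect_identical(r1@p, r2@p)
  expect_gte(r1@p, 1 / 1e5)
})

test_that("batch tests match the scalar test feature by feature", {
  set.seed(24)
  n <- 10; m <- 7
  pre <- matrix(rnorm(n * m), n)
  post <- pre + matrix(rnorm(n * m, 0.3), n)
  bt <- pairedPermutationTests(pre, post)
  for (k in seq_len(m)) {
    sc <- signPermutationTest(pre[, k], post[, k])
    expect_equal(bt$p[k], sc@p, tolerance = 1e-12)
    expect_equal(bt$observedD[k], sc@observedD, tolerance = 1e-12)
    expect_equal(bt$effectSizeD[k], sc@effectSizeD, tolerance = 1e-12)
    expect_equal(bt$power[k], sc@power, tolerance = 1e-12)
  }
})

test_that("Cohen's d uses the pooled standard deviation", {
  expect_error(cohensDPooled(rep(1, 5), rep(1, 5)), "pooled")
  set.seed(25)
  pre <- rnorm(12)
  pre <- (pre - mean(pre)) / sd(pre)          # mean 0, SD 1 exactly
  post <- pre + 1                              # mean 1, SD 1, pooled SD 1
  expect_equal(cohensDPooled(pre, post), 1, tolerance = 1e-12)
  expect_equal(cohensDPooled(post, pre), -1, tolerance = 1e-12)
  expect_equal(cohensDPooled(pre, pre), 0)
})

test_that("one-sample t power matches numeric integration of the noncentral t", {
  expect_equal(powerOneSample(c(-1, 1, -1, 1, -1, 1)), 0.05, tolerance = 1e-12)
  # oracle: integrate the noncentral-t density over the rejection region
  n <- 12; es <- 1.2
  diffs <- scale(rnorm(n))[, 1] + es           # mean/SD = 1.2 exactly
  diffs <- (diffs - mean(diffs)) / sd(diffs) + es
  ncp <- sqrt(n) * es
  tc <- qt(0.975, n - 1)
  # the noncentral-t density warns about precision in the far tail; the
  # integral is still accurate to well below the comparison tolerance
  oracle <- suppressWarnings(
    integrate(function(t) dt(t, n - 1, ncp), tc, Inf)$value +
      integrate(function(t) dt(t, n - 1, ncp), -Inf, -tc)$value)
  expect_equal(powerOneSample(diffs), oracle, tolerance = 1e-4)
  # monotone in |mean/SD| at fixed n
  pw <- vapply(seq(0.2, 2, by = 0.2), function(e) {
    d <- (scale(rnorm(n))[, 1]); d <- (d - mean(d)) / sd(d) + e
    powerOneSample(d)
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("Bonferroni thresholds reproduce the regional and edgewise constants", {
  expect_equal(bonferroniThreshold(0.05, 76), 0.05 / 76)
  expect_equal(round(bonferroniThreshold(0.05, 76), 5), 0.00066)
  expect_equal(bonferroniThreshold(0.05, 2850), 1.75e-5, tolerance = 0.01)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
})

test_that("BH selection implements the step-up rule", {
  # hand-run: k = 4 since 0.04 <= 4 * 0.05 / 5
  expect_equal(bhFdrSelect(c(0.001, 0.01, 0.02, 0.04, 0.9)), 1:4)
  expect_equal(bhFdrSelect(rep(1, 10)), integer(0))
  expect_equal(bhFdrSelect(numeric(0)), integer(0))
  # everything below alpha/m dominates Bonferroni and is selected
  expect_equal(bhFdrSelect(rep(0.05 / 20, 20) / 2), 1:20)
  # unsorted input: selection by value, not position
  expect_setequal(bhFdrSelect(c(0.9, 0.001, 0.04, 0.01, 0.02)), c(2, 3, 4, 5))
})

test_that("FDR subnetworks count within-subnetwork degree per region", {
  et <- data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 3, 4),
                   p = c(0.001, 0.9, 0.8, 0.7),
                   observedD = c(-0.5, 0.1, 0.2, 0.1))
  sn <- buildFdrSubnetwork(et, band = 2, alpha = 0.05, nRegions = 4)
  expect_equal(nrow(subnetworkEdges(sn)), 1)
  expect_equal(unname(subnetworkDegree(sn)), c(1L, 1L, 0L, 0L))
  expect_equal(subnetworkEdges(sn)$direction, -1L)
  # empty subnetwork allowed
  et$p <- rep(0.9, 4)
  sn0 <- buildFdrSubnetwork(et, band = 1, nRegions = 4)
  expect_equal(nrow(subnetworkEdges(sn0)), 0)
  expect_equal(unname(subnetworkDegree(sn0)), rep(0L, 4))
})

test_that("permutation resolution reflects realization and sample-size limits", {
  expect_equal(permutationResolution(1e6), 1e-6)
  expect_equal(permutationResolution(1e6, nSubjects = 12), 2^-12)
  expect_equal(permutationResolution(100, nSubjects = 12), 1 / 100)
})
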