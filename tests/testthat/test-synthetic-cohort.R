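test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- cohortSpec(nSubjects = 3, nRegions = 8, nVolumes = 64, seed = 5)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  for (s in 1:3) {
    expect_identical(roiData(a@pre[[s]]), roiData(b@pre[[s]]))
    expect_identical(roiData(a@post[[s]]), roiData(b@post[[s]]))
  }
  # a different seed changes the draws
  c2 <- generateCohort(cohortSpec(nSubjects = 3, nRegions = 8,
                                  nVolumes = 64, seed = 6))
  expect_false(identical(roiData(a@pre[[1]]), roiData(c2@pre[[1]])))
})

test_that("planted band-specific correlations are recovered by the analysis", {
  ee <- data.frame(i = 1L, j = 2L, band = 1L, delta = 0.6)
  spec <- cohortSpec(nSubjects = 3, nRegions = 6, nVolumes = 2000,
                     baseConnectivity = diag(6), effectEdges = ee, seed = 11)
  co <- generateCohort(spec)
  r <- vapply(co@post, function(ts)
    bandValues(bandConnectivity(sdwtDecompose(ts), 1))[1, 2], numeric(1))
  for (v in r) expect_equal(v, 0.6, tolerance = 0.05)
  # the same edge stays null at baseline and in the other bands
  rpre <- bandValues(bandConnectivity(sdwtDecompose(co@pre[[1]]), 1))[1, 2]
  expect_lt(abs(rpre), 0.1)
  r3 <- bandValues(bandConnectivity(sdwtDecompose(co@post[[1]]), 3))[1, 2]
  expect_lt(abs(r3), 0.1)
  # ground truth records the requested analysis-scale targets
  expect_equal(co@groundTruth$post[[1]][1, 2], 0.6)
  expect_equal(co@groundTruth$pre[[1]][1, 2], 0)
})

test_that("with no planted effect, paired differences are centred on zero", {
  # across 50 small cohorts: paired connectivity differences are unbiased
  # (pooled mean within 3 SE of 0) with no grossly biased edge
  nC <- 50
  diffs <- vapply(seq_len(nC), function(k) {
    spec <- cohortSpec(nSubjects = 4, nRegions = 5, nVolumes = 64,
                       baseConnectivity = modularTemplate(5, 2, 0.4, 0.1),
                       seed = 1000 + k)
    co <- generateCohort(spec)
    d <- vapply(seq_len(4), function(s) {
      post <- edgeVector(bandConnectivity(sdwtDecompose(co@post[[s]]), 2))
      pre <- edgeVector(bandConnectivity(sdwtDecompose(co@pre[[s]]), 2))
      post - pre
    }, numeric(10))
    rowMeans(d)
  }, numeric(10))
  m <- rowMeans(diffs)
  se <- apply(diffs, 1, sd) / sqrt(nC)
  z <- m / se
  # pooled over the 10 edges the mean z-score is ~N(0, 1/10) under the null
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  # no single edge shows gross bias
  expect_true(all(abs(z) < 4))
})

test_that("null-cohort edge p-values follow the permutation null distribution", {
  # one 76-region null cohort; with 12 subjects the directional exhaustive
  # test is uniform on the achievable grid {1..2^11}/2^12 (each directional
  # rank is hit by a sign vector and its negation), so the centred rank
  # transform u = (p * 4096 - 0.5)/2048 is approximately U(0, 1).
  # Regions are independent (identity template) so the 2850 edge p-values
  # are close enough to independent for the KS reference distribution.
  co <- generateCohort(cohortSpec(nSubjects = 12, baseConnectivity = diag(76),
                                  seed = 77))
  pre <- t(vapply(co@pre, function(ts)
    edgeVector(bandConnectivity(sdwtDecompose(ts), 1)), numeric(2850)))
  post <- t(vapply(co@post, function(ts)
    edgeVector(bandConnectivity(sdwtDecompose(ts), 1)), numeric(2850)))
  p <- pairedPermutationTests(pre, post)$p
  u <- (p * 4096 - 0.5) / 2048
  expect_true(all(u > 0 & u < 1))
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible planted effects are rejected naming the edge", {
  ee <- data.frame(i = 1L, j = 2L, band = 1L, delta = 0.9)
  spec <- cohortSpec(nSubjects = 2, nRegions = 6, nVolumes = 64,
                     baseConnectivity = modularTemplate(6, 2, 0.5, 0.0),
                     effectEdges = ee, seed = 1)
  # 0.5 + 0.9 = 1.4 is outside [-1, 1]
  expect_error(generateCohort(spec), "outside")
  # a value that is in range but breaks positive semidefiniteness
  S <- modularTemplate(9, 3, 0.9, 0.0)
  ee2 <- data.frame(i = c(1L, 2L), j = c(4L, 5L), band = 1L,
                    delta = c(-0.95, 0.95))
  spec2 <- cohortSpec(nSubjects = 2, nRegions = 9, nVolumes = 64,
                      baseConnectivity = S, effectEdges = ee2, seed = 1,
                      noiseSd = 0)
  expect_error(generateCohort(spec2), "\\(1, 4\\)|\\(2, 5\\)|positive semidefinite|infeasible")
})

test_that("motion traces exceed both thresholds exactly at the spikes", {
  tr <- generateMotionTrace(20, integer(0), seed = 2)
  expect_true(all(tr@fd <= 0.5) && all(tr@dvars <= 8))
  tr1 <- generateMotionTrace(20, 11, seed = 2)
  expect_gt(tr1@fd[11], 0.5)
  expect_gt(tr1@dvars[11], 8)
  expect_equal(which(tr1@fd > 0.5), 11)
  expect_equal(which(tr1@dvars > 8), 11)
  # boundary spikes
  trb <- generateMotionTrace(20, c(1, 20), seed = 3)
  expect_equal(which(trb@fd > 0.5), c(1, 20))
  expect_equal(which(!computeScrubMask(trb)), c(1, 2, 3, 19, 20))
  expect_error(generateMotionTrace(10, 11))
})

test_that("toy graphs have their closed-form properties", {
  rl <- makeToyGraph("ring_lattice", n = 76, k = 4)
  # ring lattice clustering 3(k-2)/(4(k-1)) = 0.5 at k = 4
  expect_equal(unname(nodalClustering(rl)), rep(0.5, 76))
  expect_equal(unname(igraph::degree(rl)), rep(4, 76))
  k5 <- makeToyGraph("complete", n = 5)
  expect_equal(igraph::edge_density(k5), 1)
  expect_equal(unname(nodalClustering(k5)), rep(1, 5))
  p3 <- makeToyGraph("path", n = 3)
  expect_equal(unname(igraph::degree(p3)), c(1, 2, 1))
  expect_error(makeToyGraph("ring_lattice", n = 10, k = 3), "even")
})

test_that("cohorts round-trip through TSV plus manifest", {
  spec <- cohortSpec(nSubjects = 2, nRegions = 6, nVolumes = 40, seed = 9)
  co <- generateCohort(spec)
  dir <- tempfile("cohort_")
  mpath <- writeCohort(co, dir)
  expect_true(file.exists(mpath))
  loaded <- readManifest(mpath)
  expect_equal(length(loaded$pre), 2)
  expect_equal(roiData(loaded$pre[[1]]), roiData(co@pre[[1]]),
               tolerance = 1e-12)
  expect_equal(roiData(loaded$post[[2]]), roiData(co@post[[2]]),
               tolerance = 1e-12)
  expect_equal(loaded$tr, 2)
})

test_that("clinical scores follow the stated linear model of a network feature", {
  spec <- cohortSpec(nSubjects = 12, nRegions = 6, nVolumes = 256,
                     baseConnectivity = diag(6),
                     effectEdges = data.frame(i = 1L, j = 2L, band = 1L,
                                              delta = 0.5),
                     clinicalSim = list(edge = c(1L, 2L), band = 1L,
                                        slope = -20, intercept = -5,
                                        noiseSd = 0.01),
                     seed = 13)
  co <- generateCohort(spec)
  cl <- co@clinical
  expect_equal(nrow(cl), 12)
  # with tiny noise the change is essentially intercept + slope * feature
  expect_equal(cl$change, -5 - 20 * cl$featureChange, tolerance = 0.05)
  expect_equal(cl$change, cl$postScore - cl$preScore, tolerance = 1e-12)
})
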