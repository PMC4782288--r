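# DCE-MRI enhancement maps and per-tumor summaries.

makeSeries <- function(rsiCurve, nVox = 1, baseline = 100, nb = 10, dt = 4.8) {
  nFrames <- nb + length(rsiCurve)
  sig <- array(baseline, c(nVox, 1, 1, nFrames))
  for (j in seq_along(rsiCurve)) sig[, , , nb + j] <- baseline * rsiCurve[j]
  DynamicSeries(sig, dt, nb)
}

test_that("a constant voxel has unit RSI, zero AUC, and is non-enhancing", {
  ser <- makeSeries(rep(1, 20))
  maps <- computeEnhancementMaps(ser)
  expect_equal(maps@rsi1min[1, 1, 1], 1)
  expect_equal(maps@auc1min[1, 1, 1], 0)
  expect_false(maps@enhancingMask[1, 1, 1])
})

test_that("the enhancing threshold keeps 1.5 and excludes 1.4", {
  for (rsi in c(1.4, 1.5, 1.7)) {
    ser <- makeSeries(rep(rsi, 20))
    maps <- computeEnhancementMaps(ser)
    expect_equal(maps@rsi1min[1, 1, 1], rsi)
    expect_equal(maps@enhancingMask[1, 1, 1], rsi >= 1.5)
  }
})

test_that("step enhancement reproduces the hand-computed trapezoid", {
  # unit relative enhancement from the first post-injection frame onward;
  # integrand 0 at the injection anchor, then 1 at 4.8, 9.6, ..., 62.4 s:
  # 0.5*(0+1)*4.8 + 11*4.8 + 2.4 = 57.6
  ser <- makeSeries(rep(2, 20))
  maps <- computeEnhancementMaps(ser)
  expect_equal(maps@auc1min[1, 1, 1], 57.6)
  # RSI read at the frame nearest 60 s, ties to the later frame (62.4 s)
  curve <- c(rep(2, 12), 3, rep(2, 7))
  maps2 <- computeEnhancementMaps(makeSeries(curve))
  expect_equal(maps2@rsi1min[1, 1, 1], 3)
})

test_that("AUC is invariant under global signal rescaling", {
  g <- generateDceSeries(shape = c(6, 6, 2), enhancingFraction = 0.5,
                         noiseSd = 0, seed = 4)
  m1 <- computeEnhancementMaps(g$series)
  scaled <- DynamicSeries(g$series@signal * 7.3, frameInterval(g$series),
                          baselineFrames(g$series), roi(g$series))
  m2 <- computeEnhancementMaps(scaled)
  expect_equal(m1@auc1min, m2@auc1min, tolerance = 1e-12)
})

test_that("raising post-injection samples cannot decrease AUC", {
  set.seed(11)
  base <- 1 + cumsum(runif(20, 0, 0.05))
  m1 <- computeEnhancementMaps(makeSeries(base))
  bumped <- base + runif(20, 0, 0.2)
  m2 <- computeEnhancementMaps(makeSeries(bumped))
  expect_gte(m2@auc1min[1, 1, 1], m1@auc1min[1, 1, 1])
})

test_that("voxels with non-positive baseline are excluded as invalid", {
  sig <- array(100, c(2, 1, 1, 30))
  sig[2, 1, 1, ] <- 0
  maps <- computeEnhancementMaps(DynamicSeries(sig, 4.8, 10))
  expect_true(maps@validRoi[1, 1, 1])
  expect_false(maps@validRoi[2, 1, 1])
})

test_that("too-short series and missing baseline are rejected", {
  sig <- array(100, c(1, 1, 1, 15))
  expect_error(computeEnhancementMaps(DynamicSeries(sig, 4.8, 10)),
               "too short")
  expect_error(computeEnhancementMaps(DynamicSeries(sig, 4.8, 1)),
               "baseline")
})

test_that("tumor summaries report enhancing-median AUC and exact FEV", {
  g <- generateDceSeries(shape = c(10, 10, 10), enhancingFraction = 0.4,
                         noiseSd = 0, seed = 3)
  s <- summarizeTumor(computeEnhancementMaps(g$series), day = 0)
  expect_equal(s$fev, g$truth$trueFev)
  expect_equal(s$fev, 0.4)
  # all voxels enhancing with identical AUC
  ser <- makeSeries(rep(2, 20), nVox = 5)
  s2 <- summarizeTumor(computeEnhancementMaps(ser), day = 0)
  expect_equal(s2$fev, 1)
  expect_equal(s2$medianAuc, 57.6)
  # no enhancing voxels: FEV 0 and missing median
  s3 <- summarizeTumor(computeEnhancementMaps(makeSeries(rep(1.2, 20))), day = 0)
  expect_equal(s3$fev, 0)
  expect_true(is.na(s3$medianAuc))
})

test_that("longitudinal deltas difference consecutive days", {
  su <- data.frame(day = c(0, 4, 7), medianAuc = c(10, 10, 7),
                   fev = c(0.5, 0.6, 0.4), nEnhancing = 1, nRoi = 2)
  d <- longitudinalDelta(su)
  expect_equal(d$interval, c("0-4", "4-7"))
  expect_equal(d$deltaMedianAuc, c(0, -3))
  expect_equal(d$deltaFev, c(0.1, -0.2), tolerance = 1e-12)
  expect_warning(longitudinalDelta(su[1, ]), "fewer than two")
})
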