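# Spectral preprocessing and PLS-DA chemometrics.

test_that("zero line broadening is the identity and widths add for Lorentzians", {
  ppm <- seq(3.3, 3.2, by = -0.000025)   # 0.015 Hz steps at 600 MHz
  gamma1 <- 0.5 / 600                     # 1.0 Hz FWHM in ppm
  y <- gamma1^2 / ((ppm - 3.25)^2 + gamma1^2)
  s <- SpectrumSet(rbind(a = y), ppm, factor("control"))

  ident <- preprocessSpectra(s, lineBroadeningHz = 0)
  expect_equal(intensities(ident)[1, ], y, ignore_attr = TRUE)

  lb <- preprocessSpectra(s, lineBroadeningHz = 0.3)
  fw <- measureFWHM(ppm * 600, intensities(lb)[1, ])
  expect_lt(abs(fw - 1.3) / 1.3, 0.02)
})

test_that("baseline correction removes a smooth polynomial offset", {
  ppm <- seq(4, 3, by = -0.001)
  base <- 0.4 + 0.3 * (ppm - 3.5) + 0.2 * (ppm - 3.5)^2
  g <- 0.0025
  peak <- g^2 / ((ppm - 3.5)^2 + g^2)
  s <- SpectrumSet(rbind(a = base + peak), ppm, factor("control"))
  out <- preprocessSpectra(s, lineBroadeningHz = 0, doBaseline = TRUE)
  resid <- intensities(out)[1, ] - peak
  expect_lt(max(abs(resid[abs(ppm - 3.5) > 0.05])), 0.02)
})

test_that("mean normalization yields unit means and scale invariance", {
  s <- SpectrumSet(rbind(a = rep(7, 50), b = runif(50) + 0.5),
                   seq(4, 3.02, by = -0.02), factor(c("control", "treated")))
  n1 <- meanNormalize(s)
  expect_true(all(abs(rowMeans(intensities(n1)) - 1) < 1e-12))
  expect_equal(intensities(n1)[1, ], rep(1, 50), ignore_attr = TRUE)
  s10 <- SpectrumSet(intensities(s) * 10, ppmAxis(s), classLabels(s))
  expect_equal(intensities(meanNormalize(s10)), intensities(n1),
               tolerance = 1e-12)
  sZero <- SpectrumSet(rbind(a = rep(0, 50), b = runif(50)),
                       ppmAxis(s), factor(c("control", "treated")))
  expect_error(meanNormalize(sZero), "zero-mean")
})

test_that("well-separated classes are perfectly cross-validated", {
  sp <- generateSpectraCohort(nPerClass = 6,
                              classEffects = c(PCho = 1.5, GPC = 0.6),
                              noiseSd = 0.01, seed = 7)
  spc <- cropPpm(meanNormalize(sp), c(3.0, 3.5))
  fit <- fitPLSDA(spc, 2)
  expect_equal(fit@cvSensitivity, 1)
  expect_equal(fit@cvSpecificity, 1)
  # scores of the two classes separate along LV1
  lv1 <- fit@scores[, 1]
  expect_true(max(lv1[fit@labels == "control"]) <
                min(lv1[fit@labels == "treated"]) ||
              min(lv1[fit@labels == "control"]) >
                max(lv1[fit@labels == "treated"]))
})

test_that("VIP scores satisfy the mean-square identity and rank the effects", {
  sp <- generateSpectraCohort(nPerClass = 6, noiseSd = 0.01, seed = 8)
  spc <- cropPpm(meanNormalize(sp), c(3.0, 3.5))
  fit <- fitPLSDA(spc, 2)
  v <- vipScores(fit)
  expect_lt(abs(mean(v^2) - 1), 1e-9)
  top2 <- sort(ppmAxis(spc)[order(v, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(3.23, 3.24), tolerance = 1e-9)
})

test_that("a single discriminating variable attains the maximum VIP", {
  set.seed(12)
  n <- 12
  X <- matrix(rnorm(n * 20, sd = 0.05), n, 20)
  y <- rep(c("control", "treated"), each = 6)
  X[, 7] <- X[, 7] + ifelse(y == "treated", 1, 0)
  s <- SpectrumSet(X, seq(2, 2 - 19 * 0.01, by = -0.01), factor(y))
  fit <- fitPLSDA(s, 2)
  expect_equal(which.max(vipScores(fit)), 7L)
})

test_that("degenerate PLS-DA inputs are rejected", {
  s <- generateSpectraCohort(nPerClass = 3, seed = 1,
                             ppm = seq(3.5, 3.0, by = -0.01))
  expect_error(fitPLSDA(s, ncomp = 10), "ncomp")
  one <- SpectrumSet(matrix(rnorm(4 * 5), 4, 5), seq(2, 1.92, by = -0.02),
                     factor(rep("control", 4)))
  expect_error(fitPLSDA(one, 1), "two classes")
})

test_that("the permutation p value follows the add-one convention and is never zero", {
  sp <- generateSpectraCohort(nPerClass = 4, noiseSd = 0.01, seed = 9,
                              ppm = seq(3.5, 3.0, by = -0.005))
  res <- plsdaPermutationTest(sp, ncomp = 2, nPermutations = 99, seed = 2)
  expect_equal(res$pValue,
               (sum(res$permutedStats >= res$observedStat) + 1) / 100)
  expect_gt(res$pValue, 0)
  expect_equal(res$nPermutations, 99L)
  expect_error(plsdaPermutationTest(sp, nPermutations = 0), "nPermutations")
  # strong separation at these settings: p attains the smallest value 1/100
  expect_equal(res$observedStat, 1)
})

test_that("NIPALS PLS-DA agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  sp <- generateSpectraCohort(nPerClass = 6, noiseSd = 0.01, seed = 10,
                              ppm = seq(3.5, 3.0, by = -0.005))
  spc <- meanNormalize(sp)
  fit <- fitPLSDA(spc, 2)
  mo <- mixOmics::plsda(intensities(spc), classLabels(spc), ncomp = 2,
                        scale = FALSE)
  # first latent variable agrees up to sign (later LVs differ between the
  # PLS1 and two-column-dummy PLS2 formulations)
  expect_gt(abs(cor(fit@scores[, 1], mo$variates$X[, 1])), 0.99)
  # and the two models classify the training samples identically
  moPred <- predict(mo, intensities(spc))$class$max.dist[, 2]
  b <- xenovasc:::plsCoefficients(
    xenovasc:::plsNipals(scale(intensities(spc), scale = FALSE),
                         ifelse(classLabels(spc) == "treated", 1, -1), 2))
  mine <- ifelse(sweep(intensities(spc), 2, colMeans(intensities(spc))) %*% b
                 >= 0, "treated", "control")
  expect_equal(as.character(moPred), as.character(mine), ignore_attr = TRUE)
})
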