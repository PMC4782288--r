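# Histology quantification: HSV segmentation, watershed nucleus separation,
# PEC density and immature vessel fraction.

blankMasks <- function(shape, lectin = NULL, ki67 = NULL, sma = NULL) {
  z <- matrix(FALSE, shape[1], shape[2])
  structure(list(lectin = if (is.null(lectin)) z else lectin,
                 ki67 = if (is.null(ki67)) z else ki67,
                 sma = if (is.null(sma)) z else sma,
                 thresholds = defaultStainBands()), class = "StainMasks")
}

disk2d <- function(shape, cen, r) {
  outer(seq_len(shape[1]), seq_len(shape[2]),
        function(i, j) (i - cen[1])^2 + (j - cen[2])^2 <= r^2)
}

test_that("a pure-white field segments to empty masks", {
  img <- array(1, c(32, 32, 3))
  masks <- segmentStains(StainField(img, 1))
  expect_false(any(masks$lectin) || any(masks$ki67) || any(masks$sma))
})

test_that("painted stain areas are recovered exactly", {
  h <- generateHistologyField(sizePx = c(256, 256), umPerPx = 1, nNuclei = 10,
                              fracInVessel = 0.3, nVessels = 2, seed = 21)
  masks <- segmentStains(h$field)
  expect_identical(masks$lectin, h$vesselMask)
  expect_identical(masks$ki67, h$ki67Mask)
  expect_equal(sum(masks$lectin), h$truth$vesselAreaPx)
})

test_that("invalid threshold bands are rejected", {
  bad <- defaultStainBands()
  bad$lectin$h <- c(-0.2, 0.5)
  f <- StainField(array(1, c(8, 8, 3)), 1)
  expect_error(segmentStains(f, bad), "invalid h band")
})

test_that("watershed separates touching nuclei", {
  shape <- c(128, 128)
  one <- disk2d(shape, c(40, 40), 10)
  expect_equal(max(separateNuclei(one, expectedDiameterPx = 20)), 1)
  # two overlapping disks of radius 10 with centres 14 px apart
  two <- disk2d(shape, c(80, 60), 10) | disk2d(shape, c(80, 74), 10)
  expect_equal(max(separateNuclei(two, expectedDiameterPx = 20)), 2)
  # empty mask: zero labels
  expect_equal(max(separateNuclei(matrix(FALSE, 16, 16))), 0)
})

test_that("nucleus counts match the phantom for overlap separations >= 0.6 diameters", {
  h <- generateHistologyField(sizePx = c(512, 512), umPerPx = 1, nNuclei = 25,
                              fracInVessel = 0, nVessels = 0,
                              overlapPairFrac = 0.4, nucleusDiameterUm = 16,
                              seed = 31)
  labels <- separateNuclei(h$ki67Mask, expectedDiameterPx = 16)
  expect_equal(max(labels), h$truth$nucleusCountTotal)
  expect_equal(max(labels), 25)
})

test_that("PEC density counts centroid-in-vessel nuclei per vessel area", {
  shape <- c(200, 200)
  # vessel rectangle of exactly 20,000 px = 0.02 mm^2 at 1 um/px
  lectin <- matrix(FALSE, shape[1], shape[2])
  lectin[1:100, 1:200] <- TRUE                       # 20,000 px
  labels <- matrix(0L, shape[1], shape[2])
  cen <- rbind(cbind(seq(20, 84, by = 16), 50),      # 5 centroids inside
               cbind(seq(112, 184, by = 12), 150))   # 7 centroids outside
  for (i in seq_len(nrow(cen))) labels[disk2d(shape, cen[i, ], 5)] <- i
  res <- pecDensity(labels, blankMasks(shape, lectin = lectin), umPerPx = 1)
  expect_equal(res$nPec, 5L)
  expect_equal(res$nKi67Total, 12L)
  expect_equal(res$vesselAreaMm2, 0.02)
  expect_equal(res$pecDensity, 250)
})

test_that("no nuclei means no proliferating endothelial cells", {
  res <- pecDensity(matrix(0L, 32, 32),
                    blankMasks(c(32, 32), lectin = matrix(TRUE, 32, 32)),
                    umPerPx = 1)
  expect_equal(res$nPec, 0L)
  # zero vessel area: density undefined
  res2 <- pecDensity(matrix(0L, 32, 32), blankMasks(c(32, 32)), umPerPx = 1)
  expect_true(is.na(res2$pecDensity))
})

test_that("pooled PEC density is invariant to field partitioning", {
  h1 <- list(nPec = 3L, nKi67Total = 8L, vesselAreaMm2 = 0.01)
  h2 <- list(nPec = 5L, nKi67Total = 9L, vesselAreaMm2 = 0.03)
  pooled <- poolPecResults(list(h1, h2))
  expect_equal(pooled$pecDensity, (3 + 5) / 0.04)
  # order invariance
  expect_equal(poolPecResults(list(h2, h1))$pecDensity, pooled$pecDensity)
})

test_that("immature fraction follows the component-level 5 um rule", {
  shape <- c(120, 200)
  # two lectin components of 300 and 700 px
  lectin <- matrix(FALSE, shape[1], shape[2])
  lectin[11:40, 11:20] <- TRUE                     # 300 px
  lectin[61:95, 11:30] <- TRUE                     # 700 px
  sma <- matrix(FALSE, shape[1], shape[2])
  sma[96:98, 11:30] <- TRUE                        # adjacent to the 700 px one
  res <- immatureVesselFraction(blankMasks(shape, lectin = lectin, sma = sma),
                                umPerPx = 1, minDistUm = 5)
  expect_equal(res$immatureFraction, 0.30)
  expect_equal(res$immatureAreaPx, 300L)

  # no pericyte staining at all: everything immature
  resAll <- immatureVesselFraction(blankMasks(shape, lectin = lectin),
                                   umPerPx = 1)
  expect_equal(resAll$immatureFraction, 1)
  # every component touching pericytes: nothing immature
  smaAll <- sma
  smaAll[41:43, 11:20] <- TRUE
  resNone <- immatureVesselFraction(
    blankMasks(shape, lectin = lectin, sma = smaAll), umPerPx = 1)
  expect_equal(resNone$immatureFraction, 0)
  # empty lectin mask: undefined
  expect_true(is.na(immatureVesselFraction(blankMasks(shape),
                                           umPerPx = 1)$immatureFraction))
})

test_that("adding pericyte pixels can only decrease the immature fraction", {
  set.seed(5)
  shape <- c(100, 100)
  lectin <- disk2d(shape, c(30, 30), 12) | disk2d(shape, c(70, 70), 9)
  sma <- matrix(FALSE, shape[1], shape[2])
  prev <- immatureVesselFraction(blankMasks(shape, lectin = lectin, sma = sma),
                                 umPerPx = 2)$immatureFraction
  for (i in 1:5) {
    sma[sample.int(100, 1), sample.int(100, 1)] <- TRUE
    cur <- immatureVesselFraction(blankMasks(shape, lectin = lectin, sma = sma),
                                  umPerPx = 2)$immatureFraction
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("phantom fields give exact end-to-end histology ground truth", {
  h <- generateHistologyField(sizePx = c(384, 384), umPerPx = 0.5,
                              nNuclei = 12, fracInVessel = 0.5, nVessels = 3,
                              seed = 41)
  q <- quantifyField(h$field)
  expect_equal(max(q$labels), 12)
  expect_equal(q$pec$nPec, h$truth$nucleusCountInVessel)
  expect_equal(q$pec$nPec, 6L)

  h2 <- generateHistologyField(sizePx = c(384, 384), umPerPx = 1, nNuclei = 0,
                               fracInVessel = 0, withSma = TRUE,
                               fracImmature = 0, nVessels = 5, seed = 42)
  masks <- segmentStains(h2$field)
  r <- immatureVesselFraction(masks, 1)
  expect_equal(h2$truth$immatureAreaPx, 0L)
  expect_equal(r$immatureFraction, 0)
})
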