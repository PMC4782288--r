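# Micro-CT morphometry: distance transform, local thickness, vesselness,
# FBV, caliber and distance metrics.

test_that("exact distance transform matches brute-force nearest-vessel search", {
  for (seed in 1:5) {
    dims <- c(sample(8:16, 1), sample(8:16, 1), sample(8:16, 1))
    m <- randomMask(dims, 0.04, seed = seed)
    expect_equal(xenovasc:::edtVoxels(m), bruteForceEDT(m), tolerance = 1e-12)
  }
})

test_that("local thickness matches the brute-force inscribed-sphere oracle", {
  for (seed in 1:4) {
    dims <- c(14, 13, 12)
    m <- randomBlobMask(dims, nBalls = 3, seed = seed)
    expect_equal(localThickness(m, voxelSize = 1), bruteForceLocalThickness(m),
                 tolerance = 1e-12)
  }
})

test_that("digital ball and cylinder thickness follow the diameter", {
  d <- c(17, 17, 17)
  g <- as.matrix(expand.grid(1:17, 1:17, 1:17))
  ball <- array(colSums((t(g) - c(9, 9, 9))^2) <= 25, d)
  lt <- localThickness(ball, voxelSize = 9)
  # central thickness ~ 10 voxels = 90 um (within one voxel digitally)
  expect_lt(abs(lt[9, 9, 9] - 90), 9)

  cyl <- xenovasc:::rasterizeTubeMask(c(40, 24, 24), c(1, 12, 12),
                                      c(40, 12, 12), 4)
  lt2 <- localThickness(cyl, voxelSize = 9)
  expect_lt(abs(lt2[20, 12, 12] - 2 * 4 * 9), 9)
  # empty mask: empty map
  expect_true(all(localThickness(array(FALSE, c(8, 8, 8))) == 0))
})

test_that("vesselness responds to tubes, not to constant volumes or blobs", {
  shape <- c(48, 48, 48)
  flat <- VolumeImage(array(0.5, shape), 9)
  segFlat <- vesselnessFilter(flat, scales = c(9, 18))
  expect_true(all(vesselness(segFlat) == 0))
  expect_false(any(vesselMask(segFlat)))

  # cylinder and sphere of equal brightness in one volume
  cyl <- xenovasc:::rasterizeTubeMask(shape, c(6, 14, 14), c(43, 14, 14), 4)
  sph <- xenovasc:::rasterizeTubeMask(shape, c(24, 34, 34), c(24, 34, 34), 4)
  vox <- array(0.1, shape)
  vox[cyl | sph] <- 1
  seg <- vesselnessFilter(VolumeImage(vox, 9), scales = c(9, 18, 36))
  expect_gt(max(vesselness(seg)[cyl]), max(vesselness(seg)[sph]))
})

test_that("a bright cylinder is segmented with high recall and few false positives", {
  shape <- c(48, 48, 48)
  cyl <- xenovasc:::rasterizeTubeMask(shape, c(6, 24, 24), c(43, 24, 24), 4)
  vox <- array(0.1, shape)
  vox[cyl] <- 1
  vox <- vox + array(rnorm(prod(shape), 0, 0.01), shape)
  seg <- vesselnessFilter(VolumeImage(vox, 9), scales = c(9, 18, 36))
  expect_gte(sum(vesselMask(seg) & cyl) / sum(cyl), 0.90)
  expect_lte(sum(vesselMask(seg) & !cyl) / sum(!cyl), 0.05)
})

test_that("scales below one voxel are rejected", {
  v <- VolumeImage(array(0, c(32, 32, 32)), 9)
  expect_error(vesselnessFilter(v, scales = c(4)), "one voxel")
})

test_that("FBV is the voxel-count ratio of vessel to tumor mask", {
  shape <- c(32, 32, 32)
  vol <- VolumeImage(array(0, shape), 9)
  emptySeg <- array(FALSE, shape)
  expect_equal(computeFBV(emptySeg, vol), 0)
  expect_equal(computeFBV(tumorMask(vol), vol), 1)
  # ground-truth mask injected: exact ratio
  m <- array(FALSE, shape)
  m[seq_len(round(0.05 * prod(shape)))] <- TRUE
  expect_equal(computeFBV(m, vol), sum(m) / prod(shape))
  # empty tumor mask errors
  volEmpty <- VolumeImage(array(0, shape), 9, array(FALSE, shape))
  expect_error(computeFBV(m, volEmpty), "empty tumor mask")
})

test_that("caliber metrics pin percentile interpolation and the strict cut", {
  allSmall <- rep(90, 50)
  cm <- caliberMetrics(allSmall)
  expect_equal(cm$vcP90, 90)
  expect_equal(cm$fracVcGtCut, 0)
  mixed <- c(rep(90, 80), rep(180, 20))
  cm2 <- caliberMetrics(mixed)
  expect_equal(cm2$fracVcGtCut, 0.20)
  # a caliber exactly at the cut is NOT counted as large
  expect_equal(caliberMetrics(c(rep(150, 10), 90))$fracVcGtCut, 0)
  expect_equal(sum(cm2$histogram$density), 1)
  expect_error(caliberMetrics(numeric(0)), "no vessel voxels")
})

test_that("distance-to-nearest-vessel metrics are exact and monotone under dilation", {
  shape <- c(24, 24, 24)
  vol <- VolumeImage(array(0, shape), 9)
  vessel <- array(FALSE, shape)
  vessel[12, 12, 12] <- TRUE
  dm <- dnvMetrics(vessel, vol)
  expect_equal(dm$dnvMap[13, 12, 12], 9)             # face-adjacent voxel
  expect_equal(dm$dnvMap[12, 12, 12], 0)             # vessel voxel itself

  # single straight line: lateral offsets follow the analytic point-line distance
  line <- array(FALSE, shape)
  line[, 12, 12] <- TRUE
  dl <- dnvMetrics(line, vol)
  for (k in c(1, 3, 7)) expect_equal(dl$dnvMap[5, 12 + k, 12], 9 * k)

  # dilating the vessel mask can only decrease distances
  dil <- vessel
  dil[11:13, 11:13, 11:13] <- TRUE
  dd <- dnvMetrics(dil, vol)
  nonV <- !dil
  expect_true(all(dd$dnvMap[nonV] <= dm$dnvMap[nonV] + 1e-12))
  expect_error(dnvMetrics(array(FALSE, shape), vol), "empty vessel mask")
})

test_that("designed far-voxel fraction is recovered exactly from an injected mask", {
  shape <- c(30, 30, 30)
  vessel <- array(FALSE, shape)
  vessel[1, 1, 1] <- TRUE
  dAll <- bruteForceEDT(vessel) * 9
  nonVessel <- which(!vessel)
  ord <- nonVessel[order(dAll[nonVessel])]
  far <- ord[dAll[ord] > 200]
  near <- ord[dAll[ord] <= 200]
  tumor <- array(FALSE, shape)
  tumor[c(near[1:766], far[1:234])] <- TRUE
  tumor[1, 1, 1] <- TRUE
  vol <- VolumeImage(array(0, shape), 9, tumor)
  dm <- dnvMetrics(vessel, vol)
  expect_equal(dm$fracDnvGtCut, 0.234)
})
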