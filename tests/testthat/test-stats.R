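# Nonparametric comparisons, summaries, tumor volume and 4PL calibration.

test_that("small-sample U tests are exact and match known cases", {
  cmp <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(uStatistic(cmp), 0)
  expect_equal(pValue(cmp), 1 / 3, tolerance = 1e-12)
  expect_equal(cmp@method, "exact")

  tied <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pValue(tied), 1)

  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact p matches the enumeration oracle on random tie-free samples", {
  set.seed(71)
  for (i in 1:200) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- rnorm(na); b <- rnorm(nb)
    cmp <- mannWhitneyU(a, b)
    expect_equal(cmp@method, "exact")
    expect_equal(pValue(cmp), enumerationMWOracle(a, b), tolerance = 1e-12)
  }
})

test_that("U statistics of the two groups conserve nA * nB", {
  set.seed(72)
  for (i in 1:25) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    u1 <- uStatistic(mannWhitneyU(a, b))
    u2 <- uStatistic(mannWhitneyU(b, a))
    expect_equal(u1 + u2, length(a) * length(b))
  }
})

test_that("the approximation path agrees with the reference implementation", {
  set.seed(73)
  for (i in 1:20) {
    a <- rnorm(9); b <- rnorm(8)
    mine <- pValue(mannWhitneyU(a, b))
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("median +/- MAD matches hand computations and its invariances", {
  expect_equal(medianMAD(5), c(median = 5, mad = 0))
  expect_equal(medianMAD(c(1, 2, 4)), c(median = 2, mad = 1))
  expect_equal(medianMAD(c(2, 4, 6, 8)), c(median = 5, mad = 2))
  set.seed(74)
  x <- rnorm(11)
  base <- medianMAD(x)
  shifted <- medianMAD(x + 3)
  expect_equal(shifted[["median"]], base[["median"]] + 3)
  expect_equal(shifted[["mad"]], base[["mad"]])
  scaled <- medianMAD(2.5 * x)
  expect_equal(scaled[["mad"]], 2.5 * base[["mad"]])
  expect_error(medianMAD(numeric(0)), "at least one")
})

test_that("caliper volume and baseline normalization follow the formulas", {
  expect_equal(tumorVolume(0, 0), 0)
  expect_equal(tumorVolume(6, 6), 108)
  expect_warning(v <- tumorVolume(4, 6), "swapping")
  expect_equal(v, 0.5 * 6 * 16)
  ns <- normalizeVolumeSeries(c(100, 180, 250), c(-1, 4, 8))
  expect_equal(ns$normalizedVolume, c(1, 1.8, 2.5))
})

test_that("4PL calibration round-trips and handles range exclusion", {
  x <- c(3.9, 7.8, 15.6, 31.2, 62.5, 125, 250, 500)
  y <- 0.1 + (1.5 - 0.1) / (1 + (x / 50)^1.1)
  m <- fitFourPL(x, y)
  expect_equal(m$c, 50, tolerance = 1e-4)
  # inflection identity: absorbance at c reads back c
  expect_equal(invertFourPL(m, predictFourPL(m, m$c)), m$c, tolerance = 1e-6)
  # forward-inverse round trip
  expect_equal(invertFourPL(m, predictFourPL(m, 12.5)), 12.5,
               tolerance = 1e-6 * 12.5)
  # out-of-range absorbances are NA
  expect_true(is.na(invertFourPL(m, 1.6)))

  q <- pge2Quantify(c(predictFourPL(m, 20), predictFourPL(m, 20), 5),
                    data.frame(conc = x, absorbance = y),
                    dilution = 2, rnaNg = 100)
  expect_equal(q$concentration, 40, tolerance = 1e-4)
  expect_equal(q$perNgRna, 0.4, tolerance = 1e-4)
  expect_equal(q$nUsed, 2L)
  expect_true(q$excluded[3])
})
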