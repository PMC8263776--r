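# Uniform images whose post-bleach channels change only inside the bleach
# ROI (the unbleached control region is genuinely unbleached).
flatFretSet <- function(donorPre, donorPost, accPre, accPost, shape = c(16L, 16L)) {
  rois <- fluorQuant:::defaultFretRois(shape)
  dPost <- matrix(donorPre, shape[1], shape[2])
  dPost[rois$bleach] <- donorPost
  aPost <- matrix(accPre, shape[1], shape[2])
  aPost[rois$bleach] <- accPost
  new("FretImageSet",
      donorPre = matrix(donorPre, shape[1], shape[2]),
      donorPost = dPost,
      acceptorPre = matrix(accPre, shape[1], shape[2]),
      acceptorPost = aPost,
      bleachRoi = rois$bleach, controlRoi = rois$control, cellId = "flat")
}

test_that("acceptor bleach depth follows its definition", {
  expect_equal(acceptorBleachDepth(flatFretSet(100, 100, 100, 20)), 0.8)
  expect_equal(acceptorBleachDepth(flatFretSet(100, 100, 100, 100)), 0)
  fs <- simulateFretPair(eTrue = 0.1, bleachDepthTrue = 0.8)
  expect_equal(acceptorBleachDepth(fs), 0.8)
  expect_error(acceptorBleachDepth(flatFretSet(100, 100, 0, 0)), "zero")
})

test_that("scan-loss correction uses the unbleached control region", {
  expect_equal(scanCorrectionFactor(flatFretSet(100, 100, 50, 50)), 1)
  fs <- simulateFretPair(eTrue = 0.2, scanLossTrue = 0.05)
  expect_equal(scanCorrectionFactor(fs), 0.95)
  r <- computeFretEfficiency(fs)
  expect_equal(r@fAfterCorrected, r@fAfterRaw / 0.95)
  # correcting when there is no scan loss changes nothing
  fs0 <- simulateFretPair(eTrue = 0.2, scanLossTrue = 0)
  expect_equal(scanCorrectionFactor(fs0), 1)
})

test_that("efficiency is the donor dequenching ratio, with closed form", {
  # arithmetic-forced cases via a donor-only construction
  r <- computeFretEfficiency(flatFretSet(100, 100, 100, 20))
  expect_equal(fretEfficiency(r), 0)
  r2 <- computeFretEfficiency(flatFretSet(75, 100, 100, 20))
  expect_equal(fretEfficiency(r2), 100 * 25 / 75)
  expect_equal(r2@efficiencyCanonicalPct, 25)

  # generator round trip: E_app = 100 * beta * E / (1 - E)
  r3 <- computeFretEfficiency(simulateFretPair(0.2, 0.8))
  expect_equal(fretEfficiency(r3), 20, tolerance = 0.01)
  r4 <- computeFretEfficiency(simulateFretPair(0.2, 1.0))
  expect_equal(fretEfficiency(r4), 25, tolerance = 0.01)

  expect_error(simulateFretPair(1.0), "eTrue")
  expect_error(computeFretEfficiency(flatFretSet(0, 0, 100, 20)),
               "pre-bleach donor")
})

test_that("zero transfer gives exactly zero for any bleach depth and scan loss", {
  for (beta in c(0.6, 0.8, 1)) {
    for (s in c(0, 0.05, 0.1)) {
      r <- computeFretEfficiency(simulateFretPair(0, beta, scanLossTrue = s))
      expect_equal(fretEfficiency(r), 0)
    }
  }
})

test_that("the noiseless pipeline matches 100*beta*E/(1-E) on a grid", {
  worst <- 0
  prev <- -Inf
  for (beta in seq(0.6, 1, by = 0.1)) {
    effs <- vapply(seq(0.05, 0.4, by = 0.05), function(E) {
      fretEfficiency(computeFretEfficiency(simulateFretPair(E, beta)))
    }, 0)
    expected <- 100 * beta * seq(0.05, 0.4, by = 0.05) /
      (1 - seq(0.05, 0.4, by = 0.05))
    worst <- max(worst, max(abs(effs - expected)))
    expect_true(all(diff(effs) > 0))  # strictly increasing in E
  }
  expect_lt(worst, 0.1)
})

test_that("the QC gate mirrors the required bleach depth", {
  expect_true(computeFretEfficiency(simulateFretPair(0.1, 0.8))@passedQc)
  expect_false(computeFretEfficiency(simulateFretPair(0.1, 0.5))@passedQc)
  expect_true(computeFretEfficiency(simulateFretPair(0.1, 0.5),
                                    qcMinBleach = 0.4)@passedQc)
})

test_that("group summaries are plain mean and SEM over QC passers", {
  s <- summarizeGroup(c(10, 20, 30), "demo")
  expect_equal(s$mean, 20)
  expect_equal(s$sem, 5.774, tolerance = 1e-3)
  expect_equal(s$n, 3L)
  s1 <- summarizeGroup(12.5, "single")
  expect_true(is.na(s1$sem))

  cells <- suppressWarnings(lapply(1:30, function(i)
    computeFretEfficiency(simulateFretPair(0.2, 1.0, noiseSd = 1,
                                           seed = 100 + i,
                                           cellId = paste0("c", i)))))
  g <- summarizeGroup(cells, "sim")
  expect_equal(g$n, 30L)
  expect_lt(abs(g$mean - 25), 3 * max(g$sem, 0.2))
})
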