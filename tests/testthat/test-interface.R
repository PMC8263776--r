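test_that("TIFF and CSV round trips preserve the data", {
  cfg <- simConfig(seed = 3, nSubunits = 1, pFluor = 1, nSpots = 3,
                   nFrames = 8, imageShape = c(32L, 32L), noiseSd = 1,
                   unitIntensity = 150, bleachMeanTime = 5)
  sim <- simulateSpotPopulation(cfg)
  mov <- renderMovie(sim$truth)
  tf <- file.path(tempdir(), "mov.tif")
  writeMovieTIFF(mov, tf)
  back <- readMovieTIFF(tf)
  expect_equal(movieData(back), movieData(mov), tolerance = 1e-6)
  expect_equal(frameInterval(back), 0.1)

  img <- matrix(runif(64, 10, 500), 8)
  ti <- file.path(tempdir(), "img.tif")
  writeImageTIFF(img, ti)
  expect_equal(readImageTIFF(ti), img, tolerance = 1e-5)

  tc <- file.path(tempdir(), "traces.csv")
  writeTraceCSV(sim$traces, tc)
  tr <- readTraceCSV(tc)
  expect_equal(traceValues(tr), traceValues(sim$traces), tolerance = 1e-12)
  expect_equal(spotIds(tr), spotIds(sim$traces))

  tab <- stepCountTable(c(`1` = 5, `2` = 9, `3` = 2), kMax = 4)
  ts <- file.path(tempdir(), "counts.csv")
  writeStepCountCSV(tab, ts)
  expect_equal(stepCounts(readStepCountCSV(ts)), stepCounts(tab))
})

test_that("the counting pipeline recovers the truth end to end", {
  out <- file.path(tempdir(), "count4")
  b <- runCountingPipeline(list(seed = 1,
    simulate = list(nSubunits = 4, pFluor = 0.67, nSpots = 1012,
                    noiseSd = 0)), out)
  expect_equal(selectedN(bundleResults(b)$selection), 4L)
  expect_true(all(file.exists(bundleFiles(b))))

  out1 <- file.path(tempdir(), "count1")
  b1 <- runCountingPipeline(list(seed = 2,
    simulate = list(nSubunits = 1, pFluor = 0.67, nSpots = 500,
                    noiseSd = 0)), out1)
  expect_equal(selectedN(bundleResults(b1)$selection), 1L)
})

test_that("pipeline bundles are byte-identical across reruns", {
  cfgList <- list(seed = 9, simulate = list(nSubunits = 2, pFluor = 0.67,
                                            nSpots = 300, noiseSd = 3))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  b1 <- runCountingPipeline(cfgList, d1)
  b2 <- runCountingPipeline(cfgList, d2)
  for (f in basename(bundleFiles(b1))) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("configuration validation rejects unknown keys before any work", {
  expect_error(runCountingPipeline(list(seed = 1, simulte = list()),
                                   tempdir()), "unknown")
  expect_error(runCountingPipeline(list(seed = 1), tempdir()),
               "exactly one")
  expect_error(runFretPipeline(list(seed = 1, bogus = 2), tempdir()),
               "unknown")
  expect_error(runColocPipeline(list(seed = 1,
                                     simulate = list(ratios = 0:3),
                                     inputs = list()), tempdir()),
               "exactly one")
})

test_that("missing input files fail with the offending path named", {
  expect_error(runCountingPipeline(list(seed = 1,
                                        tracesCsv = "/nope/traces.csv"),
                                   tempdir()),
               "/nope/traces.csv")
})

test_that("the FRET pipeline reports zero transfer as zero", {
  out <- file.path(tempdir(), "fret0")
  b <- runFretPipeline(list(seed = 4,
    simulate = list(nCells = 10, eTrue = 0, bleachDepthTrue = 0.8,
                    noiseSd = 0.5)), out)
  s <- bundleResults(b)$summary
  expect_equal(s$n, 10L)
  expect_lt(abs(s$mean), 3 * s$sem + 0.05)
})

test_that("the coloc pipeline recovers the decay from images", {
  out <- file.path(tempdir(), "coloc")
  b <- runColocPipeline(list(seed = 5,
    simulate = list(ratios = seq(0, 2.5, length.out = 12), A = 0.85,
                    k = 1.4, C = 0.05)), out)
  fit <- bundleResults(b)$decay
  expect_equal(decayParams(fit), c(A = 0.85, k = 1.4, C = 0.05),
               tolerance = 0.02)
  expect_gt(rSquared(fit), 0.99)
})

test_that("a movie TIFF feeds the counting pipeline end to end", {
  cfg <- simConfig(seed = 8, nSubunits = 1, pFluor = 1, nSpots = 25,
                   nFrames = 60, imageShape = c(128L, 128L), noiseSd = 2,
                   unitIntensity = 300, backgroundLevel = 10,
                   bleachMeanTime = 1.5)
  sim <- simulateSpotPopulation(cfg)
  mov <- renderMovie(sim$truth)
  tf <- file.path(tempdir(), "pipe.tif")
  writeMovieTIFF(mov, tf)
  out <- file.path(tempdir(), "fromtiff")
  b <- runCountingPipeline(list(seed = 1, movieTiff = tf,
                                candidates = 1:2), out)
  expect_equal(selectedN(bundleResults(b)$selection), 1L)
  expect_true(nchar(provenance(b)$inputDigests[[basename(tf)]]) == 32L)
})
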