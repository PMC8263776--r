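smallMovieCfg <- function(seed = 2, nSpots = 1, nFrames = 30,
                          bleachMeanTime = 1000, noiseSd = 0, ...) {
  simConfig(seed = seed, nSubunits = 1, pFluor = 1, nSpots = nSpots,
            nFrames = nFrames, imageShape = c(64L, 64L),
            bleachMeanTime = bleachMeanTime, noiseSd = noiseSd,
            unitIntensity = 200, backgroundLevel = 10, ...)
}

test_that("rendering is static without bleaching and steps when bleaching", {
  cfg <- smallMovieCfg()  # bleach time far beyond the movie
  sim <- simulateSpotPopulation(cfg)
  mov <- renderMovie(sim$truth)
  d <- movieData(mov)
  for (f in 2:dim(d)[1]) expect_equal(d[f, , ], d[1, , ])

  # force a bleach between frames 10 and 11 and check a single clean step
  truth <- sim$truth
  truth@bleachTimes[[1]] <- 10 * cfg@frameInterval  # survives frames 1..10
  mov <- renderMovie(truth, cfg)
  tb <- truthTable(truth)
  tr <- extractTrace(mov, round(tb$row[1]), round(tb$col[1]),
                     background = cfg@backgroundLevel)
  y <- traceValues(tr)[1, ]
  expect_gt(min(y[1:10]), 150)
  expect_equal(unname(y[11:30]), rep(0, 20), tolerance = 1e-8)
  expect_equal(length(unique(round(y[1:10], 6))), 1L)
})

test_that("extractTraces sums ROI blocks and is linear", {
  arr <- array(7, c(5, 20, 20))
  mov <- new("MovieStack", data = arr, frameInterval = 0.1)
  y <- traceValues(extractTrace(mov, 10, 10, size = 6, background = 0))[1, ]
  expect_equal(unname(y), rep(252, 5))  # 36 * 7

  zero <- new("MovieStack", data = array(0, c(5, 20, 20)), frameInterval = 0.1)
  expect_equal(unname(traceValues(extractTrace(zero, 10, 10))[1, ]), rep(0, 5))

  # linearity: trace(A + B) = trace(A) + trace(B) at zero background
  a <- array(runif(5 * 20 * 20), c(5, 20, 20))
  b <- array(runif(5 * 20 * 20), c(5, 20, 20))
  movA <- new("MovieStack", data = a, frameInterval = 0.1)
  movB <- new("MovieStack", data = b, frameInterval = 0.1)
  movAB <- new("MovieStack", data = a + b, frameInterval = 0.1)
  tA <- traceValues(extractTrace(movA, 8, 12, background = 0))
  tB <- traceValues(extractTrace(movB, 8, 12, background = 0))
  tAB <- traceValues(extractTrace(movAB, 8, 12, background = 0))
  expect_equal(tAB, tA + tB)

  expect_error(extractTrace(mov, 2, 2), "outside")
})

test_that("a rendered PSF deposits the expected mass inside the ROI", {
  cfg <- smallMovieCfg()
  sim <- simulateSpotPopulation(cfg)
  tb <- truthTable(sim$truth)
  mov <- renderMovie(sim$truth)
  ctr <- c(round(tb$row[1]), round(tb$col[1]))
  tr <- extractTrace(mov, ctr[1], ctr[2], background = cfg@backgroundLevel)
  # numerically integrate the continuous PSF over the ROI pixel area
  rows <- ctr[1] + (-2:3); cols <- ctr[2] + (-2:3)
  fx <- function(x) dnorm(x, tb$row[1], cfg@psfSigma)
  fy <- function(y) dnorm(y, tb$col[1], cfg@psfSigma)
  mass <- integrate(fx, min(rows) - 0.5, max(rows) + 0.5)$value *
          integrate(fy, min(cols) - 0.5, max(cols) + 0.5)$value
  expect_equal(traceValues(tr)[1, 1], cfg@unitIntensity * mass,
               tolerance = 1e-6)
})

test_that("detection finds immobile spots and rejects drifting ones", {
  cfg <- smallMovieCfg(noiseSd = 0)
  sim <- simulateSpotPopulation(cfg)
  mov <- renderMovie(sim$truth)
  rois <- detectImmobileSpots(mov)
  expect_equal(nrow(rois), 1L)
  expect_lte(matchDistances(rois, truthTable(sim$truth)), 1)

  # ~3 px drift over the movie fails the 1 px immobility criterion
  cfgD <- smallMovieCfg(noiseSd = 0, driftPerFrame = c(0.1, 0))
  simD <- simulateSpotPopulation(cfgD)
  movD <- renderMovie(simD$truth, cfgD)
  expect_equal(nrow(detectImmobileSpots(movD)), 0L)

  # blank movie: zero ROIs
  blank <- new("MovieStack", data = array(10, c(10, 48, 48)),
               frameInterval = 0.1)
  expect_equal(nrow(detectImmobileSpots(blank)), 0L)
})

test_that("no false positives on blank noisy movies at default thresholds", {
  fp <- 0L
  for (s in 1:100) {
    arr <- withr::with_seed(1000 + s,
      array(rnorm(10 * 48 * 48, mean = 10, sd = 3), c(10, 48, 48)))
    mov <- new("MovieStack", data = arr, frameInterval = 0.1)
    fp <- fp + nrow(detectImmobileSpots(mov))
  }
  expect_equal(fp, 0L)
})

test_that("most spots of a dense field are recovered within one pixel", {
  cfg <- simConfig(seed = 21, nSubunits = 2, pFluor = 1, nSpots = 30,
                   nFrames = 40, imageShape = c(128L, 128L), noiseSd = 2,
                   unitIntensity = 200, backgroundLevel = 10,
                   bleachMeanTime = 20)
  sim <- simulateSpotPopulation(cfg)
  mov <- renderMovie(sim$truth)
  rois <- detectImmobileSpots(mov)
  tt <- truthTable(sim$truth)
  d <- matchDistances(rois, tt[tt$visible, ])
  expect_gte(sum(d <= 1), 0.95 * sum(tt$visible))
})

test_that("background estimation recovers the truth and has a fallback", {
  uni <- new("MovieStack", data = array(4.5, c(6, 40, 40)),
             frameInterval = 0.1)
  bg <- estimateBackground(uni, NULL)
  expect_equal(bg, rep(4.5, 6))
  # scaled to the ROI area on subtraction
  tr <- extractTraces(uni, data.frame(row = 20, col = 20, size = 6))
  expect_equal(unname(traceValues(tr)[1, ]), rep(0, 6))

  cfg <- smallMovieCfg(noiseSd = 3)
  sim <- simulateSpotPopulation(cfg)
  mov <- renderMovie(sim$truth)
  tb <- truthTable(sim$truth)
  rois <- data.frame(row = round(tb$row), col = round(tb$col), size = 6L)
  bg <- estimateBackground(mov, rois)
  expect_lt(max(abs(bg - cfg@backgroundLevel)),
            3 * cfg@noiseSd / sqrt(64 * 64 - 36) + 0.2)

  tiny <- new("MovieStack", data = array(1, c(3, 6, 6)), frameInterval = 0.1)
  expect_warning(estimateBackground(tiny, data.frame(row = 3, col = 3,
                                                     size = 6L)),
                 "whole image")
})
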