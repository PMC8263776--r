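rawColocSet <- function(A, B, mask = NULL, cellId = "demo") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(A), ncol(A))
  new("ColocImageSet", channels = list(A = A, B = B), cellMask = mask,
      acquisition = list(laser = 1), cellId = cellId)
}

test_that("Mander's coefficients match hand examples and limits", {
  m <- matrix(c(10, 0, 5, 0), 2)
  b <- matrix(c(0, 0, 3, 7), 2)
  cr <- mandersCoefficients(rawColocSet(m, b), "A", "B", method = "zero")
  expect_equal(mandersM1(cr), 5 / 15)
  expect_equal(mandersM2(cr), 3 / 10)

  ident <- matrix(runif(64) + 0.1, 8)
  cri <- mandersCoefficients(rawColocSet(ident, ident), "A", "B",
                             method = "zero")
  expect_equal(mandersM1(cri), 1)
  expect_equal(mandersM2(cri), 1)
  expect_equal(cri@overlapR, 1)

  dis <- matrix(0, 4, 4); dis[1:2, ] <- 3
  djs <- matrix(0, 4, 4); djs[3:4, ] <- 5
  crd <- mandersCoefficients(rawColocSet(dis, djs), "A", "B", method = "zero")
  expect_equal(mandersM1(crd), 0)
  expect_equal(mandersM2(crd), 0)

  expect_error(mandersCoefficients(rawColocSet(matrix(0, 2, 2),
                                               matrix(1, 2, 2)), "A", "B"),
               "zero total intensity")
})

test_that("coefficients swap under channel exchange and ignore gain", {
  A <- matrix(runif(100), 10); B <- matrix(runif(100), 10)
  f <- mandersCoefficients(rawColocSet(A, B), "A", "B", method = "zero")
  r <- mandersCoefficients(rawColocSet(B, A), "A", "B", method = "zero")
  expect_equal(mandersM1(f), mandersM2(r))
  expect_equal(mandersM2(f), mandersM1(r))
  # positive rescaling of the non-thresholded channel leaves M1 unchanged
  g <- mandersCoefficients(rawColocSet(3.7 * A, B), "A", "B", method = "zero")
  expect_equal(mandersM1(g), mandersM1(f))
})

test_that("simulated cells conserve reporter intensity and decay with dose", {
  pan <- simulateColocPanel(ratios = c(0, 0.5, 1, 2), A = 0.9, k = 1.5,
                            C = 0, seed = 6)
  geom <- colocCellGeometry()
  for (i in seq_along(pan$sets)) {
    rep_ <- pan$sets[[i]]@channels$reporter
    total <- 100 * sum(geom$cell)
    expect_equal(sum(rep_[geom$er]) + sum(rep_[geom$mb]), total)
    expect_equal(sum(rep_), total)
  }
  expect_true(all(diff(pan$truth$erFractionTrue) <= 0))
  expect_equal(pan$truth$erFractionTrue[1], 0.9)            # exp(0) = 1
  expect_equal(pan$truth$erFractionTrue[3], 0.9 * exp(-1.5),
               tolerance = 1e-12)

  # determinism: identical ratios and seed give identical images
  pan2 <- simulateColocPanel(ratios = c(0, 0.5, 1, 2), A = 0.9, k = 1.5,
                             C = 0, seed = 6)
  expect_identical(pan$sets[[2]]@channels, pan2$sets[[2]]@channels)

  expect_error(simulateColocCell(1, A = 0.9, C = 0.2), "A \\+ C")
  badGeom <- colocCellGeometry()
  badGeom$er[] <- FALSE
  expect_error(simulateColocCell(1, geometry = badGeom), "nonempty")
})

test_that("per-cell ratio analysis recovers the generative curve", {
  pan <- simulateColocPanel(ratios = c(0, 1), A = 0.9, k = 1.5, C = 0,
                            seed = 7)
  pts <- perCellRatioAnalysis(pan$sets)
  expect_equal(pts$ratio, c(0, 1), tolerance = 1e-9)
  expect_equal(pts$erColoc[2], 0.9 * exp(-1.5), tolerance = 1e-6)

  # regulator absent: ratio 0 and erColoc is the plain reporter/ER M1
  s <- pan$sets[[1]]
  s@channels$regulator[] <- 0
  expect_equal(perCellRatioAnalysis(list(s))$ratio, 0)

  # mismatched acquisition settings are refused
  sets <- pan$sets
  sets[[2]]@acquisition <- list(laser = 2, gain = 1)
  expect_error(perCellRatioAnalysis(sets), "acquisition settings differ")
})

test_that("exponential-decay fitting is exact on model points", {
  x <- seq(0, 2, by = 0.25)
  fit <- fitExponentialDecay(data.frame(x = x, y = 0.9 * exp(-1.5 * x)))
  expect_equal(decayParams(fit), c(A = 0.9, k = 1.5, C = 0), tolerance = 1e-6)
  expect_equal(rSquared(fit), 1, tolerance = 1e-6)

  flat <- fitExponentialDecay(data.frame(x = x, y = rep(0.4, length(x))))
  expect_true(flat@flat)
  expect_equal(flat@rate, 0)
  expect_equal(rSquared(flat), 0)

  expect_error(fitExponentialDecay(data.frame(x = c(1, 1, 1, 1),
                                              y = c(1, 2, 3, 4))),
               "degenerate")
  expect_error(fitExponentialDecay(data.frame(x = 1:3, y = 1:3)), "4 points")
})

test_that("decay estimates are unbiased at the 30-cell design", {
  xs <- seq(0, 3, length.out = 30)
  est <- t(vapply(1:100, function(s) {
    pts <- simulateDecayPoints(xs, A = 0.9, k = 1.5, C = 0.05,
                               noiseSd = 0.05, seed = 1500 + s)
    decayParams(fitExponentialDecay(pts))
  }, c(A = 0, k = 0, C = 0)))
  expect_lt(abs(mean(est[, "A"]) - 0.9), 0.02)
  expect_lt(abs(mean(est[, "k"]) - 1.5), 0.06)
  expect_lt(abs(mean(est[, "C"]) - 0.05), 0.01)
})

test_that("the fitter never loses to a coarse grid search on SSE", {
  for (s in 1:5) {
    pts <- simulateDecayPoints(seq(0, 3, length.out = 25), A = 0.8, k = 1.2,
                               C = 0.1, noiseSd = 0.05, seed = 400 + s)
    fit <- fitExponentialDecay(pts)
    expect_lte(fit@sse, gridDecaySSE(pts$x, pts$y) + 1e-9)
  }
})

test_that("fitted rates order correctly across true rates", {
  ks <- c(0.3, 0.8, 1.5, 2.5, 4)
  kh <- vapply(ks, function(k) {
    pts <- data.frame(x = seq(0, 3, length.out = 20),
                      y = 0.9 * exp(-k * seq(0, 3, length.out = 20)))
    fitExponentialDecay(pts)@rate
  }, 0)
  expect_equal(cor(kh, ks, method = "spearman"), 1)
})
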