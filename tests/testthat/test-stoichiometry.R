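test_that("the conditional PMF matches exhaustive enumeration", {
  for (n in 1:6) {
    for (p in seq(0.05, 0.95, by = 0.05)) {
      expect_lt(max(abs(conditionalBinomialPmf(n, p, 1:n) -
                        enumConditionalPmf(n, p, 1:n))), 1e-12)
      expect_lt(abs(sum(conditionalBinomialPmf(n, p, 1:n)) - 1), 1e-12)
    }
  }
})

test_that("PMF hand values and argument checks", {
  expect_equal(conditionalBinomialPmf(1, 0.3, 1), 1.0)
  expect_equal(conditionalBinomialPmf(2, 0.5, 1), 2 / 3)
  expect_equal(conditionalBinomialPmf(2, 0.5, 2), 1 / 3)
  pmf4 <- conditionalBinomialPmf(4, 0.67, 1:4)
  expect_equal(pmf4[4], 0.20393, tolerance = 1e-4)
  expect_equal(which.max(pmf4), 3L)
  expect_equal(pmf4[3], 0.40177, tolerance = 1e-4)
  expect_error(conditionalBinomialPmf(2, 0.5, 3), "1..n")
  expect_error(conditionalBinomialPmf(2, 0, 1), "p")
})

test_that("maximum-likelihood p recovers known tables (grid oracle)", {
  # table exactly proportional to the conditional PMF at p = 0.67
  counts <- round(10000 * conditionalBinomialPmf(4, 0.67, 1:4))
  fit <- fitBinomialP(stepCountTable(counts), n = 4)
  expect_lt(abs(detectionProb(fit) - 0.67), 1e-3)
  expect_lt(abs(detectionProb(fit) - gridFitP(counts, 4)), 1e-3)
  expect_true(detectionProb(fit) >= detectionProbCI(fit)[1] &&
              detectionProb(fit) <= detectionProbCI(fit)[2])
  expect_equal(sum(expectedFreqs(fit)), 1)

  fit2 <- fitBinomialP(stepCountTable(c(`1` = 667, `2` = 333)), n = 2)
  expect_lt(abs(detectionProb(fit2) - 0.5), 1e-3)
  expect_lt(abs(detectionProb(fit2) - gridFitP(c(667, 333), 2)), 1e-3)

  # monomer: the conditional model is p-free
  fit1 <- fitBinomialP(stepCountTable(c(`1` = 500)), n = 1)
  expect_equal(detectionProb(fit1), 1.0)
  expect_true(fit1@flatLikelihood)

  # counts beyond n: lack of fit warned, not an error
  expect_warning(f <- fitBinomialP(stepCountTable(c(`1` = 10, `2` = 10)), 1),
                 "lack of fit")
  expect_true(f@lackOfFit)
  expect_equal(f@logLik, -Inf)
})

test_that("likelihood maximisation matches the dense grid oracle", {
  for (s in 1:20) {
    tab <- withr::with_seed(s, {
      n <- sample(2:4, 1)
      p <- runif(1, 0.3, 0.9)
      as.vector(rmultinom(1, 800, conditionalBinomialPmf(n, p, 1:n)))
    })
    n <- length(tab)
    fit <- fitBinomialP(stepCountTable(tab, kMax = 4), n = n)
    expect_lt(abs(detectionProb(fit) - gridFitP(tab, n)), 1e-3)
  }
})

test_that("AIC model selection discriminates oligomeric states", {
  expect_equal(selectedN(selectStoichiometry(stepCountTable(c(`1` = 5000),
                                                            kMax = 4))), 1L)
  expect_equal(selectedN(selectStoichiometry(
    stepCountTable(c(`1` = 248, `2` = 252), kMax = 4))), 2L)
  counts <- round(1000 * conditionalBinomialPmf(4, 0.67, 1:4))
  expect_equal(selectedN(selectStoichiometry(stepCountTable(counts))), 4L)
})

test_that("selection and coverage hold over multinomial replicates", {
  hits <- 0L; covered <- 0L
  for (s in 1:100) {
    counts <- withr::with_seed(2000 + s,
      as.vector(rmultinom(1, 1000, conditionalBinomialPmf(4, 0.67, 1:4))))
    tab <- stepCountTable(counts, kMax = 4)
    sel <- selectStoichiometry(tab)
    if (selectedN(sel) == 4L) hits <- hits + 1L
    ci <- detectionProbCI(sel@fits$n4)
    if (ci[1] <= 0.67 && 0.67 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(hits, 95L)
  expect_gte(covered, 93L)

  # monomer / dimer discrimination at N = 500
  for (n in c(1L, 2L)) {
    ok <- 0L
    for (s in 1:100) {
      counts <- withr::with_seed(3000 + 100 * n + s,
        as.vector(rmultinom(1, 500, conditionalBinomialPmf(n, 0.67, 1:n))))
      if (selectedN(selectStoichiometry(stepCountTable(counts, kMax = 4)))
          == n) ok <- ok + 1L
    }
    expect_gte(ok, 95L)
  }
})

test_that("mixture fitting resolves pure populations and keeps weights valid", {
  suppressMessages({
    mix <- fitStoichiometryMixture(stepCountTable(c(`1` = 496, `2` = 504)),
                                   p = 0.67)
    expect_gt(mixtureWeights(mix)[["2"]], 0.95)
    expect_equal(sum(mixtureWeights(mix)), 1, tolerance = 1e-9)

    mono <- fitStoichiometryMixture(stepCountTable(c(`1` = 1000), kMax = 2),
                                    p = 0.67)
    expect_lt(mixtureWeights(mono)[["2"]], 0.05)
    expect_true(mono@boundary)

    free <- fitStoichiometryMixture(stepCountTable(c(`1` = 300, `2` = 350,
                                                     `3` = 50)),
                                    components = c(2L, 4L))
    expect_equal(sum(mixtureWeights(free)), 1, tolerance = 1e-9)
  })
  expect_message(fitStoichiometryMixture(stepCountTable(c(`1` = 10, `2` = 10)),
                                         p = 0.67), "confounded")
})

test_that("goodness of fit matches hand computation and pools sparse cells", {
  counts <- round(600 * conditionalBinomialPmf(3, 0.6, 1:3))
  tab <- stepCountTable(counts)
  g <- goodnessOfFit(tab, n = 3, p = 0.6)
  expect_lt(g$statistic, 0.01)  # only integer rounding of the counts

  # dimer expectation at p = 0.67, N = 500: expected counts 248.12 / 251.88
  g2 <- goodnessOfFit(stepCountTable(c(`1` = 248, `2` = 252)), n = 2, p = 0.67)
  expect_equal(g2$statistic, 1.224e-4, tolerance = 0.05)
  expect_equal(g2$df, 1)

  # impossible cell under a monomer model is pooled with a warning
  expect_warning(
    g3 <- goodnessOfFit(stepCountTable(c(`1` = 480, `2` = 20)), n = 1, p = 1),
    "pooled")
  expect_true(is.finite(g3$statistic))
  expect_error(goodnessOfFit(stepCountTable(c(`1` = 480), kMax = 1),
                             n = 1, p = 1), "2 usable cells")
})
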