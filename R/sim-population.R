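#' @include AllClasses.R utils.R
NULL

#' Create a simulation configuration
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults describe a typical
#' single-molecule TIRF bleaching acquisition: a 512 x 512 px EMCCD field,
#' 100 ms frames, 50 s movies, ~10 s mean single-fluorophore bleach time,
#' 100 a.u. per fluorophore with Gaussian noise of 5 a.u., and a PSF sigma
#' of 1.2 px with spots kept at least 8 px apart (the low-density condition
#' that guarantees one complex per diffraction-limited spot).
#'
#' @param seed integer master seed.
#' @param nSubunits true subunit count per complex (1 = monomer, 2 = dimer,
#'   4 = tetramer).
#' @param pFluor probability that one fluorophore tag is fluorescent.
#' @param nSpots number of simulated complexes.
#' @param nFrames movie length in frames.
#' @param frameInterval seconds per frame.
#' @param unitIntensity summed intensity per fluorophore, a.u.
#' @param bleachMeanTime exponential mean bleach time, seconds.
#' @param noiseSd additive Gaussian noise s.d., a.u.
#' @param backgroundLevel background level, a.u.
#' @param imageShape integer (rows, cols) in pixels.
#' @param psfSigma PSF standard deviation, pixels.
#' @param minSpotSeparation minimum pairwise spot distance, pixels.
#' @param driftPerFrame linear drift (rows, cols) per frame in pixels.
#' @param noiseModel "gaussian" or "poisson".
#' @param blipRate probability per trace of one spurious upward blip.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, nSubunits = 2, nSpots = 100)
#' cfg
#' @export
simConfig <- function(seed = 1L, nSubunits = 4L, pFluor = 0.67,
                      nSpots = 1000L, nFrames = 500L, frameInterval = 0.1,
                      unitIntensity = 100, bleachMeanTime = 10,
                      noiseSd = 5, backgroundLevel = 10,
                      imageShape = c(512L, 512L), psfSigma = 1.2,
                      minSpotSeparation = 8, driftPerFrame = c(0, 0),
                      noiseModel = "gaussian", blipRate = 0) {
  for (nm in c("seed", "nSubunits", "nSpots", "nFrames")) {
    v <- get(nm)
    stopIfNot(length(v) == 1 && is.finite(v) && v == round(v),
              sprintf("'%s' must be a single finite integer", nm))
  }
  new("SimConfig", seed = as.integer(seed), nSubunits = as.integer(nSubunits),
      pFluor = as.numeric(pFluor), nSpots = as.integer(nSpots),
      nFrames = as.integer(nFrames), frameInterval = as.numeric(frameInterval),
      unitIntensity = as.numeric(unitIntensity),
      bleachMeanTime = as.numeric(bleachMeanTime),
      noiseSd = as.numeric(noiseSd), backgroundLevel = as.numeric(backgroundLevel),
      imageShape = as.integer(imageShape), psfSigma = as.numeric(psfSigma),
      minSpotSeparation = as.numeric(minSpotSeparation),
      driftPerFrame = as.numeric(driftPerFrame),
      noiseModel = as.character(noiseModel), blipRate = as.numeric(blipRate))
}

# Place nSpots points uniformly in the field with pairwise distance
# >= minSep, using a bucket grid for neighbour lookups. Errors when the
# field cannot host the requested density after bounded retries.
placeSpots <- function(nSpots, shape, minSep, margin) {
  lo <- margin + 1
  hiR <- shape[1] - margin
  hiC <- shape[2] - margin
  stopIfNot(hiR > lo && hiC > lo,
            "image_shape too small for the PSF/ROI margin")
  cell <- minSep
  nbR <- ceiling((hiR - lo + 1) / cell)
  nbC <- ceiling((hiC - lo + 1) / cell)
  buckets <- vector("list", nbR * nbC)
  pts <- matrix(NA_real_, nSpots, 2)
  placed <- 0L
  tries <- 0L
  maxTries <- 200L * nSpots
  while (placed < nSpots) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("spot placement failed after ", maxTries,
           " attempts: too many spots for the field at this separation",
           call. = FALSE)
    r <- stats::runif(1, lo, hiR)
    c <- stats::runif(1, lo, hiC)
    br <- min(nbR, 1L + floor((r - lo) / cell))
    bc <- min(nbC, 1L + floor((c - lo) / cell))
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- br + dr; cc <- bc + dc
      if (rr < 1 || rr > nbR || cc < 1 || cc > nbC) next
      for (id in buckets[[(cc - 1L) * nbR + rr]]) {
        if ((pts[id, 1] - r)^2 + (pts[id, 2] - c)^2 < minSep^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (!ok) next
    placed <- placed + 1L
    pts[placed, ] <- c(r, c)
    key <- (bc - 1L) * nbR + br
    buckets[[key]] <- c(buckets[[key]], placed)
  }
  pts
}

# Per-frame surviving-fluorophore counts for every spot (spots x frames).
# A fluorophore with bleach time t contributes to frames 1..ceiling(t/dt);
# frame f is stamped at time (f-1)*dt.
survivorMatrix <- function(bleachTimes, nFrames, dt) {
  nSpots <- length(bleachTimes)
  nFluor <- lengths(bleachTimes)
  allT <- unlist(bleachTimes, use.names = FALSE)
  surv <- matrix(nFluor, nSpots, nFrames)
  if (!length(allT)) return(surv)
  spotRep <- rep.int(seq_len(nSpots), nFluor)
  idx <- pmin(ceiling(allT / dt), nFrames + 1L)
  cnt <- tabulate((idx - 1L) * nSpots + spotRep, nbins = nSpots * (nFrames + 1L))
  M <- matrix(cnt, nSpots, nFrames + 1L)
  # cumulative bleached before frame f = sum of decrements with idx <= f-1
  cum <- apply(M, 1L, cumsum)             # (nFrames+1) x nSpots
  bled <- t(rbind(0, cum[seq_len(nFrames - 1L), , drop = FALSE]))
  surv - bled
}

#' Simulate a truth-tagged spot population with bleaching traces
#'
#' Draws, per spot, a fluorescent-fluorophore count from
#' Binomial(nSubunits, pFluor), independent exponential bleach times, and a
#' position respecting the minimum-separation (low-density) constraint.
#' Each emitted trace is the summed-ROI intensity
#' \code{unitIntensity * survivors(t) + background + noise}, returned
#' background-subtracted with the subtracted background recorded. Spots
#' with zero fluorescent fluorophores are invisible in a real experiment;
#' they are truth-tagged but excluded from the emitted traces unless
#' \code{includeInvisible = TRUE}.
#'
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param includeInvisible emit traces for dark spots too (oracle use).
#' @return list with elements \code{truth} (\linkS4class{SpotTruth}) and
#'   \code{traces} (\linkS4class{BleachTraces}).
#' @examples
#' sim <- simulateSpotPopulation(simConfig(seed = 7, nSpots = 50))
#' sim$truth
#' sim$traces
#' @export
simulateSpotPopulation <- function(config, includeInvisible = FALSE) {
  validObject(config)
  nS <- config@nSpots
  truthData <- withSeed(derivedSeed(config@seed, "population"), {
    pts <- placeSpots(nS, config@imageShape, config@minSpotSeparation,
                      margin = ceiling(3 * config@psfSigma) + 3)
    nFluor <- stats::rbinom(nS, config@nSubunits, config@pFluor)
    bt <- lapply(nFluor, function(k) {
      if (k == 0L) numeric(0) else stats::rexp(k, rate = 1 / config@bleachMeanTime)
    })
    list(pts = pts, nFluor = nFluor, bt = bt)
  })
  tb <- data.frame(
    spotId = sprintf("spot%04d", seq_len(nS)),
    row = truthData$pts[, 1], col = truthData$pts[, 2],
    nFluorescent = truthData$nFluor,
    visible = truthData$nFluor >= 1L,
    stringsAsFactors = FALSE
  )
  truth <- new("SpotTruth", table = tb, bleachTimes = truthData$bt,
               config = config)

  keep <- if (includeInvisible) seq_len(nS) else which(tb$visible)
  surv <- survivorMatrix(truthData$bt[keep], config@nFrames, config@frameInterval)
  signal <- config@unitIntensity * surv
  values <- withSeed(derivedSeed(config@seed, "traces"), {
    v <- if (config@noiseModel == "poisson") {
      lam <- signal + config@backgroundLevel
      matrix(stats::rpois(length(lam), lam), nrow(signal)) - config@backgroundLevel
    } else if (config@noiseSd > 0) {
      signal + matrix(stats::rnorm(length(signal), sd = config@noiseSd), nrow(signal))
    } else signal
    if (config@blipRate > 0 && nrow(v) > 0) {
      hit <- stats::runif(nrow(v)) < config@blipRate
      at <- sample.int(ncol(v), nrow(v), replace = TRUE)
      v[cbind(which(hit), at[hit])] <- v[cbind(which(hit), at[hit])] + config@unitIntensity
    }
    v
  })
  traces <- new("BleachTraces", values = values, spotId = tb$spotId[keep],
                frameInterval = config@frameInterval,
                background = rep(config@backgroundLevel, length(keep)))
  list(truth = truth, traces = traces)
}

#' Simulate a controlled staircase benchmark for the step detector
#'
#' Generates piecewise-constant bleaching-like traces with a known number
#' of equal-size downward steps and plateau lengths drawn uniformly from
#' \code{plateauRange} frames, ending on a background plateau of zero.
#' This is the resolvable-step regime in which exact step-count recovery is
#' a meaningful benchmark; sub-frame (coincident) bleaches are excluded by
#' construction.
#'
#' @param nTraces number of traces.
#' @param maxSteps steps per trace drawn uniformly from 1..maxSteps.
#' @param stepSize step magnitude, a.u.
#' @param plateauRange integer length-2; plateau length bounds, frames.
#' @param nFrames total trace length, frames.
#' @param noiseSd additive Gaussian noise s.d., a.u.
#' @param seed integer seed.
#' @return list with \code{traces} (\linkS4class{BleachTraces}) and
#'   \code{nStepsTrue} (integer vector).
#' @examples
#' bench <- simulateStepTraces(10, noiseSd = 20, seed = 3)
#' bench$nStepsTrue
#' @export
simulateStepTraces <- function(nTraces, maxSteps = 4L, stepSize = 100,
                               plateauRange = c(5L, 15L), nFrames = 80L,
                               noiseSd = 0, seed = 1L) {
  stopIfNot(nFrames >= (maxSteps + 1L) * max(plateauRange),
            "nFrames too short for maxSteps plateaus of plateauRange length")
  withSeed(derivedSeed(seed, "staircase"), {
    k <- sample.int(maxSteps, nTraces, replace = TRUE)
    values <- matrix(0, nTraces, nFrames)
    for (i in seq_len(nTraces)) {
      lens <- sample(seq(plateauRange[1], plateauRange[2]), k[i], replace = TRUE)
      lvl <- k[i]
      pos <- 1L
      for (j in seq_len(k[i])) {
        values[i, pos:(pos + lens[j] - 1L)] <- lvl * stepSize
        pos <- pos + lens[j]
        lvl <- lvl - 1L
      }
      # remaining frames stay at background zero
    }
    if (noiseSd > 0)
      values <- values + matrix(stats::rnorm(length(values), sd = noiseSd),
                                nTraces)
    traces <- new("BleachTraces", values = values,
                  spotId = sprintf("bench%04d", seq_len(nTraces)),
                  frameInterval = 0.1,
                  background = rep(0, nTraces))
    list(traces = traces, nStepsTrue = k)
  })
}
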