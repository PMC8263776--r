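#' @import methods
NULL

#' Simulation configuration for synthetic single-molecule data
#'
#' Holds every tunable of the synthetic-data generators: oligomer size and
#' per-subunit fluorescence probability for the binomial spot population,
#' photobleaching kinetics, optics (point-spread function width, image size,
#' spot density constraint) and the noise model. The defaults describe a
#' typical TIRF single-molecule bleaching experiment on an EMCCD camera:
#' 512x512 field, 100 ms frames, ~10 s mean single-fluorophore bleach time
#' and additive Gaussian noise.
#'
#' @slot seed integer; master seed. All stochastic stages draw from streams
#'   derived from it, so adding a stage never perturbs earlier draws.
#' @slot nSubunits integer >= 1; true subunit count per complex.
#' @slot pFluor probability in (0, 1] that a given fluorophore tag is
#'   fluorescent (folded/matured GFP).
#' @slot nSpots integer; number of complexes simulated (visible or not).
#' @slot nFrames integer; movie length in frames.
#' @slot frameInterval seconds per frame.
#' @slot unitIntensity summed-trace intensity contributed by one fluorophore
#'   (arbitrary units, a.u.).
#' @slot bleachMeanTime mean of the exponential single-fluorophore bleach
#'   time, seconds.
#' @slot noiseSd additive Gaussian noise s.d. (a.u.): per trace sample for
#'   trace simulation, per pixel for rendered movies.
#' @slot backgroundLevel background per pixel (a.u.); trace simulation uses
#'   it per trace sample.
#' @slot imageShape integer length-2 (rows, cols) in pixels.
#' @slot psfSigma isotropic Gaussian PSF s.d., pixels.
#' @slot minSpotSeparation minimum pairwise spot distance, pixels; must
#'   exceed twice the PSF sigma so spots stay diffraction-separated.
#' @slot driftPerFrame numeric length-2 (rows, cols) linear drift per frame
#'   in pixels; nonzero values are used to exercise immobility filtering.
#' @slot noiseModel "gaussian" (default) or "poisson".
#' @slot blipRate probability per trace of one spurious 1-frame upward blip
#'   (stress input for the step detector); default 0.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  seed = "integer", nSubunits = "integer", pFluor = "numeric",
  nSpots = "integer", nFrames = "integer", frameInterval = "numeric",
  unitIntensity = "numeric", bleachMeanTime = "numeric",
  noiseSd = "numeric", backgroundLevel = "numeric",
  imageShape = "integer", psfSigma = "numeric",
  minSpotSeparation = "numeric", driftPerFrame = "numeric",
  noiseModel = "character", blipRate = "numeric"
))

setValidity("SimConfig", function(object) {
  chk <- function(cond, msg) if (!isTRUE(cond)) msg else NULL
  num1 <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x)) paste0("'", nm, "' must be a single finite value") else NULL
  }
  errs <- c(
    num1(object@pFluor, "pFluor"), num1(object@frameInterval, "frameInterval"),
    num1(object@unitIntensity, "unitIntensity"), num1(object@bleachMeanTime, "bleachMeanTime"),
    num1(object@noiseSd, "noiseSd"), num1(object@backgroundLevel, "backgroundLevel"),
    num1(object@psfSigma, "psfSigma"), num1(object@minSpotSeparation, "minSpotSeparation"),
    chk(object@pFluor >= 0 && object@pFluor <= 1, "'pFluor' must lie in [0, 1]"),
    chk(object@nSubunits >= 1L, "'nSubunits' must be a positive integer"),
    chk(object@nSpots >= 1L, "'nSpots' must be a positive integer"),
    chk(object@nFrames >= 2L, "'nFrames' must be at least 2"),
    chk(object@frameInterval > 0, "'frameInterval' must be positive"),
    chk(object@unitIntensity > 0, "'unitIntensity' must be positive"),
    chk(object@bleachMeanTime > 0, "'bleachMeanTime' must be positive"),
    chk(object@noiseSd >= 0, "'noiseSd' must be non-negative"),
    chk(object@backgroundLevel >= 0, "'backgroundLevel' must be non-negative"),
    chk(length(object@imageShape) == 2L && all(object@imageShape >= 8L),
        "'imageShape' must be two integers >= 8"),
    chk(object@psfSigma > 0, "'psfSigma' must be positive"),
    chk(object@minSpotSeparation > 2 * object@psfSigma,
        "'minSpotSeparation' must exceed 2 * psfSigma (low-density condition)"),
    chk(length(object@driftPerFrame) == 2L && all(is.finite(object@driftPerFrame)),
        "'driftPerFrame' must be two finite values"),
    chk(object@noiseModel %in% c("gaussian", "poisson"),
        "'noiseModel' must be \"gaussian\" or \"poisson\""),
    chk(object@blipRate >= 0 && object@blipRate <= 1, "'blipRate' must lie in [0, 1]")
  )
  if (length(errs)) errs else TRUE
})

#' Truth-tagged simulated spot population
#'
#' Ground truth for one simulated field: per-spot position, number of
#' fluorescent fluorophores (a draw from Binomial(nSubunits, pFluor)), their
#' exponential bleach times, and visibility (at least one fluorescent tag).
#'
#' @slot table data.frame with columns spotId, row, col, nFluorescent,
#'   visible (positions are 1-based pixel coordinates).
#' @slot bleachTimes list of numeric vectors, one per spot, seconds; length
#'   equals nFluorescent.
#' @slot config the generating \linkS4class{SimConfig}.
#' @exportClass SpotTruth
setClass("SpotTruth", representation(
  table = "data.frame", bleachTimes = "list", config = "SimConfig"
))

setValidity("SpotTruth", function(object) {
  tb <- object@table
  need <- c("spotId", "row", "col", "nFluorescent", "visible")
  if (!all(need %in% names(tb))) return("truth table is missing required columns")
  if (length(object@bleachTimes) != nrow(tb)) return("one bleach-time vector per spot required")
  if (!all(lengths(object@bleachTimes) == tb$nFluorescent))
    return("length(bleachTimes) must equal nFluorescent for every spot")
  if (!all(tb$visible == (tb$nFluorescent >= 1L))) return("visible must equal nFluorescent >= 1")
  TRUE
})

#' A set of background-corrected bleaching traces
#'
#' Summed-ROI intensity versus frame for one or more spots, after
#' subtraction of the recorded per-trace background.
#'
#' @slot values numeric matrix, traces in rows, frames in columns (a.u.).
#' @slot spotId character vector of row identifiers.
#' @slot frameInterval seconds per frame.
#' @slot background numeric vector, the per-trace background that was
#'   subtracted (a.u. per frame).
#' @exportClass BleachTraces
setClass("BleachTraces", representation(
  values = "matrix", spotId = "character", frameInterval = "numeric",
  background = "numeric"
))

setValidity("BleachTraces", function(object) {
  if (nrow(object@values) != length(object@spotId)) return("one spotId per trace required")
  if (length(object@background) != nrow(object@values)) return("one background per trace required")
  if (!all(is.finite(object@background))) return("background must be finite")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  TRUE
})

#' Multi-frame grayscale movie stack
#'
#' @slot data numeric array (frame, row, col), a.u.
#' @slot frameInterval seconds per frame.
#' @exportClass MovieStack
setClass("MovieStack", representation(data = "array", frameInterval = "numeric"))

setValidity("MovieStack", function(object) {
  if (length(dim(object@data)) != 3L) return("movie data must be a 3-D array (frame, row, col)")
  if (dim(object@data)[1] < 2L) return("a movie needs at least 2 frames")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  TRUE
})

#' Change-point fit of a single bleaching trace
#'
#' @slot spotId trace identifier.
#' @slot changePoints integer vector, 1-based index of the first frame of
#'   each new plateau (a step occurs between changePoints - 1 and
#'   changePoints).
#' @slot levels fitted plateau means, a.u.; length nSteps + 1.
#' @slot nSteps integer number of steps.
#' @slot residualSd residual standard deviation around the plateaus, a.u.
#' @slot accepted logical; whether the fit passed quality control.
#' @slot reason character; rejection reason, or "ok".
#' @exportClass StepFit
setClass("StepFit", representation(
  spotId = "character", changePoints = "integer", levels = "numeric",
  nSteps = "integer", residualSd = "numeric", accepted = "logical",
  reason = "character"
))

setValidity("StepFit", function(object) {
  if (length(object@levels) != object@nSteps + 1L) return("levels must have length nSteps + 1")
  if (length(object@changePoints) != object@nSteps) return("one change point per step required")
  TRUE
})

#' Observed frequency of bleaching-step counts
#'
#' @slot counts integer vector named "1".."kMax"; number of accepted spots
#'   with k steps.
#' @slot totalSpots integer; sum of counts.
#' @slot kMax integer; largest step count tabulated.
#' @exportClass StepCountTable
setClass("StepCountTable", representation(
  counts = "integer", totalSpots = "integer", kMax = "integer"
))

setValidity("StepCountTable", function(object) {
  if (length(object@counts) != object@kMax) return("counts must have one cell per k = 1..kMax")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@totalSpots) return("totalSpots must equal sum(counts)")
  TRUE
})

#' Detection-conditional binomial fit of a step-count table
#'
#' @slot n assumed subunit count.
#' @slot pHat maximum-likelihood per-subunit fluorescence probability.
#' @slot pCI 95\% profile-likelihood interval for p.
#' @slot logLik multinomial log-likelihood at pHat, nats.
#' @slot expectedFreqs expected relative frequencies for k = 1..kMax.
#' @slot chiSquare Pearson chi-square statistic against the fit.
#' @slot df chi-square degrees of freedom.
#' @slot converged logical.
#' @slot flatLikelihood logical; TRUE when p is unidentifiable (n = 1).
#' @slot lackOfFit logical; TRUE when counts occur at k > n.
#' @exportClass BinomialFitResult
setClass("BinomialFitResult", representation(
  n = "integer", pHat = "numeric", pCI = "numeric", logLik = "numeric",
  expectedFreqs = "numeric", chiSquare = "numeric", df = "numeric",
  converged = "logical", flatLikelihood = "logical", lackOfFit = "logical"
))

#' Model selection across candidate subunit counts
#'
#' @slot table data.frame with columns n, pHat, logLik, AIC.
#' @slot selectedN subunit count with minimal AIC (ties to smaller n).
#' @slot selectionMargin AIC difference to the runner-up.
#' @slot fits list of \linkS4class{BinomialFitResult}, one per candidate.
#' @exportClass ModelSelectionResult
setClass("ModelSelectionResult", representation(
  table = "data.frame", selectedN = "integer", selectionMargin = "numeric",
  fits = "list"
))

#' Mixture fit of step counts over several oligomeric states
#'
#' @slot components data.frame with columns n, weight.
#' @slot pHat shared per-subunit fluorescence probability.
#' @slot pFixed logical; TRUE when p was held fixed.
#' @slot logLik mixture log-likelihood, nats.
#' @slot boundary logical; TRUE when the solution sits on a weight boundary.
#' @exportClass MixtureFitResult
setClass("MixtureFitResult", representation(
  components = "data.frame", pHat = "numeric", pFixed = "logical",
  logLik = "numeric", boundary = "logical"
))

setValidity("MixtureFitResult", function(object) {
  w <- object@components$weight
  if (any(w < -1e-9 | w > 1 + 1e-9)) return("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1")
  TRUE
})

#' Acceptor-photobleaching FRET image set for one cell
#'
#' Donor and acceptor images before and after acceptor photobleaching, plus
#' the bleached ROI and an unbleached control region used for scan-loss
#' correction.
#'
#' @slot donorPre,donorPost,acceptorPre,acceptorPost numeric matrices, a.u.
#' @slot bleachRoi,controlRoi logical masks, same shape, disjoint, nonempty.
#' @slot cellId character identifier.
#' @exportClass FretImageSet
setClass("FretImageSet", representation(
  donorPre = "matrix", donorPost = "matrix", acceptorPre = "matrix",
  acceptorPost = "matrix", bleachRoi = "matrix", controlRoi = "matrix",
  cellId = "character"
))

setValidity("FretImageSet", function(object) {
  dims <- lapply(list(object@donorPre, object@donorPost, object@acceptorPre,
                      object@acceptorPost, object@bleachRoi, object@controlRoi), dim)
  if (length(unique(dims)) != 1L) return("all images and masks must share one shape")
  b <- as.logical(object@bleachRoi); ctl <- as.logical(object@controlRoi)
  if (!any(b) || !any(ctl)) return("bleach and control ROIs must be nonempty")
  if (any(b & ctl)) return("bleach and control ROIs must be disjoint")
  TRUE
})

#' Per-cell acceptor-photobleaching FRET result
#'
#' @slot cellId cell identifier.
#' @slot fBefore mean donor intensity in the bleach ROI before bleaching.
#' @slot fAfterRaw mean donor intensity in the bleach ROI after bleaching.
#' @slot scanFactor donor control-region post/pre ratio (scan-loss factor).
#' @slot fAfterCorrected fAfterRaw / scanFactor.
#' @slot efficiencyPct 100 * (fAfterCorrected - fBefore) / fBefore.
#' @slot efficiencyCanonicalPct 100 * (fAfterCorrected - fBefore) /
#'   fAfterCorrected, the conventional dequenching normalisation, reported
#'   alongside for comparison.
#' @slot bleachDepth acceptor bleach depth beta in [0, 1].
#' @slot passedQc logical; beta >= the QC threshold.
#' @exportClass FretResult
setClass("FretResult", representation(
  cellId = "character", fBefore = "numeric", fAfterRaw = "numeric",
  scanFactor = "numeric", fAfterCorrected = "numeric",
  efficiencyPct = "numeric", efficiencyCanonicalPct = "numeric",
  bleachDepth = "numeric", passedQc = "logical"
))

#' Multichannel colocalization image set for one cell
#'
#' @slot channels named list of numeric matrices (e.g. reporter, er,
#'   regulator), a.u.
#' @slot cellMask logical matrix, the analysed cell footprint.
#' @slot acquisition named list of acquisition settings (laser power, gain);
#'   batch analyses require identical settings across cells.
#' @slot cellId character identifier.
#' @exportClass ColocImageSet
setClass("ColocImageSet", representation(
  channels = "list", cellMask = "matrix", acquisition = "list",
  cellId = "character"
))

setValidity("ColocImageSet", function(object) {
  if (!length(object@channels) || is.null(names(object@channels)))
    return("channels must be a named list")
  dims <- lapply(c(object@channels, list(object@cellMask)), dim)
  if (length(unique(dims)) != 1L) return("all channels and the mask must share one shape")
  if (!any(as.logical(object@cellMask))) return("cell mask must be nonempty")
  TRUE
})

#' Mander's colocalization coefficients for one cell
#'
#' @slot cellId cell identifier.
#' @slot m1 fraction of channel-A intensity on pixels where channel B is
#'   above threshold.
#' @slot m2 converse fraction for channel B.
#' @slot overlapR normalized intensity-product overlap coefficient
#'   (secondary output).
#' @slot thresholds named numeric thresholds used, with the method recorded
#'   in \code{thresholdMethod}.
#' @slot thresholdMethod character.
#' @exportClass ColocResult
setClass("ColocResult", representation(
  cellId = "character", m1 = "numeric", m2 = "numeric", overlapR = "numeric",
  thresholds = "numeric", thresholdMethod = "character"
))

setValidity("ColocResult", function(object) {
  tol <- 1e-9
  if (object@m1 < -tol || object@m1 > 1 + tol) return("M1 must lie in [0, 1]")
  if (object@m2 < -tol || object@m2 > 1 + tol) return("M2 must lie in [0, 1]")
  TRUE
})

#' Exponential-decay fit of colocalization versus expression ratio
#'
#' Model: y = A * exp(-k * x) + C, fitted by bounded nonlinear least
#' squares with deterministic multistart.
#'
#' @slot amplitude A (dimensionless, >= 0).
#' @slot rate k per ratio unit (>= 0).
#' @slot offset C in [0, 1].
#' @slot rSquared 1 - SS_res / SS_tot.
#' @slot sse residual sum of squares at the solution.
#' @slot nCells number of points fitted.
#' @slot flat logical; TRUE for a degenerate flat fit.
#' @exportClass DecayFit
setClass("DecayFit", representation(
  amplitude = "numeric", rate = "numeric", offset = "numeric",
  rSquared = "numeric", sse = "numeric", nCells = "integer", flat = "logical"
))

#' Reproducible results bundle written by a pipeline run
#'
#' @slot results named list of in-memory results.
#' @slot files character vector of files written.
#' @slot provenance named list: config echo, seed, package version, input
#'   digests. Re-running with the same provenance reproduces the bundle
#'   byte for byte.
#' @exportClass ReportBundle
setClass("ReportBundle", representation(
  results = "list", files = "character", provenance = "list"
))
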