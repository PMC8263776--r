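#' @include AllClasses.R
NULL

#' Accessors for fluorQuant classes
#'
#' Small read-only accessors for the package's S4 containers; use these in
#' preference to direct slot access.
#'
#' @param object a fluorQuant S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setMethod("truthTable", "SpotTruth", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("bleachTimes", function(object) standardGeneric("bleachTimes"))
#' @rdname accessors
#' @export
setMethod("bleachTimes", "SpotTruth", function(object) object@bleachTimes)

#' @rdname accessors
#' @export
setGeneric("simConfigOf", function(object) standardGeneric("simConfigOf"))
#' @rdname accessors
#' @export
setMethod("simConfigOf", "SpotTruth", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "BleachTraces", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("spotIds", function(object) standardGeneric("spotIds"))
#' @rdname accessors
#' @export
setMethod("spotIds", "BleachTraces", function(object) object@spotId)
#' @rdname accessors
#' @export
setMethod("spotIds", "StepFit", function(object) object@spotId)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "BleachTraces", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "MovieStack", function(object) object@frameInterval)

#' @rdname accessors
#' @export
setGeneric("movieData", function(object) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setMethod("movieData", "MovieStack", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))
#' @rdname accessors
#' @export
setMethod("nSteps", "StepFit", function(object) object@nSteps)

#' @rdname accessors
#' @export
setGeneric("changePoints", function(object) standardGeneric("changePoints"))
#' @rdname accessors
#' @export
setMethod("changePoints", "StepFit", function(object) object@changePoints)

#' @rdname accessors
#' @export
setGeneric("plateauLevels", function(object) standardGeneric("plateauLevels"))
#' @rdname accessors
#' @export
setMethod("plateauLevels", "StepFit", function(object) object@levels)

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(object) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setMethod("isAccepted", "StepFit", function(object) object@accepted)

#' @rdname accessors
#' @export
setGeneric("stepCounts", function(object) standardGeneric("stepCounts"))
#' @rdname accessors
#' @export
setMethod("stepCounts", "StepCountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("totalSpots", function(object) standardGeneric("totalSpots"))
#' @rdname accessors
#' @export
setMethod("totalSpots", "StepCountTable", function(object) object@totalSpots)

#' @rdname accessors
#' @export
setGeneric("relativeFreqs", function(object) standardGeneric("relativeFreqs"))
#' @rdname accessors
#' @export
setMethod("relativeFreqs", "StepCountTable", function(object) {
  object@counts / object@totalSpots
})

#' @rdname accessors
#' @export
setGeneric("detectionProb", function(object) standardGeneric("detectionProb"))
#' @rdname accessors
#' @export
setMethod("detectionProb", "BinomialFitResult", function(object) object@pHat)
#' @rdname accessors
#' @export
setMethod("detectionProb", "MixtureFitResult", function(object) object@pHat)

#' @rdname accessors
#' @export
setGeneric("detectionProbCI", function(object) standardGeneric("detectionProbCI"))
#' @rdname accessors
#' @export
setMethod("detectionProbCI", "BinomialFitResult", function(object) object@pCI)

#' @rdname accessors
#' @export
setGeneric("expectedFreqs", function(object) standardGeneric("expectedFreqs"))
#' @rdname accessors
#' @export
setMethod("expectedFreqs", "BinomialFitResult", function(object) object@expectedFreqs)

#' @rdname accessors
#' @export
setGeneric("selectedN", function(object) standardGeneric("selectedN"))
#' @rdname accessors
#' @export
setMethod("selectedN", "ModelSelectionResult", function(object) object@selectedN)

#' @rdname accessors
#' @export
setGeneric("candidateTable", function(object) standardGeneric("candidateTable"))
#' @rdname accessors
#' @export
setMethod("candidateTable", "ModelSelectionResult", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @rdname accessors
#' @export
setMethod("mixtureWeights", "MixtureFitResult", function(object) {
  stats::setNames(object@components$weight, object@components$n)
})

#' @rdname accessors
#' @export
setGeneric("fretEfficiency", function(object) standardGeneric("fretEfficiency"))
#' @rdname accessors
#' @export
setMethod("fretEfficiency", "FretResult", function(object) object@efficiencyPct)

#' @rdname accessors
#' @export
setGeneric("bleachDepth", function(object) standardGeneric("bleachDepth"))
#' @rdname accessors
#' @export
setMethod("bleachDepth", "FretResult", function(object) object@bleachDepth)

#' @rdname accessors
#' @export
setGeneric("mandersM1", function(object) standardGeneric("mandersM1"))
#' @rdname accessors
#' @export
setMethod("mandersM1", "ColocResult", function(object) object@m1)

#' @rdname accessors
#' @export
setGeneric("mandersM2", function(object) standardGeneric("mandersM2"))
#' @rdname accessors
#' @export
setMethod("mandersM2", "ColocResult", function(object) object@m2)

#' @rdname accessors
#' @export
setGeneric("decayParams", function(object) standardGeneric("decayParams"))
#' @rdname accessors
#' @export
setMethod("decayParams", "DecayFit", function(object) {
  c(A = object@amplitude, k = object@rate, C = object@offset)
})

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setMethod("rSquared", "DecayFit", function(object) object@rSquared)

#' @rdname accessors
#' @export
setGeneric("bundleResults", function(object) standardGeneric("bundleResults"))
#' @rdname accessors
#' @export
setMethod("bundleResults", "ReportBundle", function(object) object@results)

#' @rdname accessors
#' @export
setGeneric("bundleFiles", function(object) standardGeneric("bundleFiles"))
#' @rdname accessors
#' @export
setMethod("bundleFiles", "ReportBundle", function(object) object@files)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ReportBundle", function(object) object@provenance)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: n =", object@nSubunits, ", p =", object@pFluor,
      ",", object@nSpots, "spots,", object@nFrames, "frames @",
      object@frameInterval, "s\n")
  cat("  unit intensity", object@unitIntensity, "a.u., bleach mean",
      object@bleachMeanTime, "s, noise sd", object@noiseSd,
      paste0("(", object@noiseModel, ")"), ", background",
      object@backgroundLevel, "\n")
  cat("  field", paste(object@imageShape, collapse = "x"), "px, PSF sigma",
      object@psfSigma, "px, min separation", object@minSpotSeparation,
      "px, seed", object@seed, "\n")
})

setMethod("show", "SpotTruth", function(object) {
  tb <- object@table
  cat("SpotTruth:", nrow(tb), "spots,", sum(tb$visible), "visible;",
      "fluorophore counts ~ Binomial(", object@config@nSubunits, ",",
      object@config@pFluor, ")\n")
})

setMethod("show", "BleachTraces", function(object) {
  cat("BleachTraces:", nrow(object@values), "traces x", ncol(object@values),
      "frames @", object@frameInterval, "s\n")
})

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@data)
  cat("MovieStack:", d[1], "frames of", d[2], "x", d[3], "px @",
      object@frameInterval, "s\n")
})

setMethod("show", "StepFit", function(object) {
  cat("StepFit", object@spotId, ":", object@nSteps, "step(s),",
      if (object@accepted) "accepted" else paste("rejected:", object@reason), "\n")
  if (object@nSteps > 0)
    cat("  change points:", paste(object@changePoints, collapse = ", "), "\n")
})

setMethod("show", "StepCountTable", function(object) {
  cat("StepCountTable:", object@totalSpots, "accepted spots\n")
  print(round(rbind(count = object@counts,
                    freq = object@counts / object@totalSpots), 4))
})

setMethod("show", "BinomialFitResult", function(object) {
  cat("Conditional binomial fit, n =", object@n, ": p-hat =",
      round(object@pHat, 4))
  if (object@flatLikelihood) cat(" (flat likelihood: p unidentifiable for n = 1)")
  cat("\n  95% CI [", round(object@pCI[1], 4), ",", round(object@pCI[2], 4),
      "], logLik", round(object@logLik, 2), ", chi-square",
      signif(object@chiSquare, 4), "on", object@df, "df\n")
  if (object@lackOfFit) cat("  warning: counts observed at k > n (lack of fit)\n")
})

setMethod("show", "ModelSelectionResult", function(object) {
  cat("Stoichiometry selection: n =", object@selectedN,
      "(AIC margin", round(object@selectionMargin, 2), ")\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "MixtureFitResult", function(object) {
  cat("Oligomer mixture fit (shared p =", round(object@pHat, 4),
      if (object@pFixed) "fixed" else "fitted", ")\n")
  print(object@components, row.names = FALSE)
  if (object@boundary) cat("  note: boundary solution\n")
})

setMethod("show", "FretImageSet", function(object) {
  cat("FretImageSet", object@cellId, ":", paste(dim(object@donorPre), collapse = "x"),
      "px; bleach ROI", sum(object@bleachRoi), "px, control ROI",
      sum(object@controlRoi), "px\n")
})

setMethod("show", "FretResult", function(object) {
  cat("FRET (acceptor photobleaching)", object@cellId, ": E =",
      round(object@efficiencyPct, 2), "% , beta =",
      round(object@bleachDepth, 3), if (object@passedQc) "[QC pass]" else "[QC fail]", "\n")
})

setMethod("show", "ColocResult", function(object) {
  cat("Mander's coefficients", object@cellId, ": M1 =", round(object@m1, 4),
      ", M2 =", round(object@m2, 4), ", overlap R =", round(object@overlapR, 4),
      paste0("(", object@thresholdMethod, " thresholds)"), "\n")
})

setMethod("show", "DecayFit", function(object) {
  cat("Exponential decay fit over", object@nCells, "cells: y = A exp(-k x) + C\n")
  cat("  A =", round(object@amplitude, 4), ", k =", round(object@rate, 4),
      ", C =", round(object@offset, 4), ", R^2 =", round(object@rSquared, 4),
      if (object@flat) "(flat fit)" else "", "\n")
})

setMethod("show", "ReportBundle", function(object) {
  cat("ReportBundle:", length(object@files), "files, seed",
      object@provenance$seed, "\n")
  cat(" ", paste(basename(object@files), collapse = ", "), "\n")
})
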