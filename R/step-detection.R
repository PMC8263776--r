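#' @include AllClasses.R utils.R
NULL

#' Step-detection parameters
#'
#' @param penaltyFactor BIC-type penalty multiplier: a split is accepted
#'   only when it lowers the residual sum of squares by more than
#'   \code{penaltyFactor * log(n) * sigma^2}, with sigma estimated robustly
#'   from first differences.
#' @param minSeg minimum plateau length in frames.
#' @param mergeFrac post-pass threshold: steps smaller than this fraction
#'   of the median step magnitude are merged away.
#' @param monotone drop upward steps (bleaching is monotone; upward blips
#'   are artifacts).
#' @param kMax largest step count admissible by quality control.
#' @param maxStepRatio steps larger than this multiple of the median step
#'   magnitude flag a coincident double bleach; the fit is rejected rather
#'   than split heuristically.
#' @param minFrames shortest evaluable trace, frames.
#' @return named list of parameters.
#' @export
stepFitParams <- function(penaltyFactor = 3, minSeg = 1L, mergeFrac = 0.5,
                          monotone = FALSE, kMax = 4L, maxStepRatio = 2.5,
                          minFrames = 10L) {
  list(penaltyFactor = penaltyFactor, minSeg = as.integer(minSeg),
       mergeFrac = mergeFrac, monotone = monotone, kMax = as.integer(kMax),
       maxStepRatio = maxStepRatio, minFrames = as.integer(minFrames))
}

segMeans <- function(y, cps) {
  bounds <- c(1L, cps, length(y) + 1L)
  vapply(seq_len(length(bounds) - 1L),
         function(i) mean(y[bounds[i]:(bounds[i + 1L] - 1L)]), 0)
}

# remove upward steps (monotone mode) and steps below mergeFrac of the
# median magnitude, one at a time, refitting plateau means after each
mergeSteps <- function(y, cps, mergeFrac, monotone) {
  repeat {
    if (!length(cps)) break
    lv <- segMeans(y, cps)
    d <- diff(lv)
    drop <- integer(0)
    if (monotone && any(d > 0)) {
      drop <- which.max(d)
    } else if (length(d) >= 2L) {
      m <- stats::median(abs(d))
      small <- which(abs(d) < mergeFrac * m)
      if (length(small)) drop <- small[which.min(abs(d)[small])]
    }
    if (!length(drop)) break
    cps <- cps[-drop]
  }
  cps
}

stepFitCore <- function(y, params) {
  n <- length(y)
  if (n < params$minFrames)
    stop("trace too short to evaluate (", n, " < ", params$minFrames,
         " frames)", call. = FALSE)
  sigma <- stats::mad(diff(y)) / sqrt(2)
  thr <- params$penaltyFactor * log(n) * sigma^2 +
    1e-9 * diff(range(y))^2 + 1e-12
  cps <- binseg_changepoints(y, thr, params$minSeg)
  cps <- mergeSteps(y, cps, params$mergeFrac, params$monotone)
  lv <- segMeans(y, cps)
  fitted <- rep(lv, diff(c(1L, cps, n + 1L)))
  list(changePoints = as.integer(cps), levels = lv,
       nSteps = length(cps), residualSd = sqrt(mean((y - fitted)^2)))
}

#' Fit photobleaching steps in a single trace
#'
#' Piecewise-constant change-point fit by recursive binary segmentation:
#' each candidate split is kept only when it lowers the residual sum of
#' squares by more than a BIC-type penalty, followed by a merge pass that
#' removes steps smaller than a configurable fraction of the median step
#' size (and, in monotone mode, upward steps). Plateau levels are the
#' sample means between change points; the fit is deterministic for a
#' given trace and parameters, and invariant to adding a constant to the
#' whole trace.
#'
#' @param y numeric trace (background-corrected summed ROI intensity per
#'   frame), or a \linkS4class{BleachTraces} (use \code{index} to pick one).
#' @param params list from \code{\link{stepFitParams}}.
#' @param spotId identifier for the returned fit.
#' @param index trace row when \code{y} is a \linkS4class{BleachTraces}.
#' @return a \linkS4class{StepFit} (not yet quality-controlled; see
#'   \code{\link{acceptTrace}}).
#' @examples
#' y <- rep(c(200, 100, 0), each = 15)
#' fitSteps(y)
#' @export
fitSteps <- function(y, params = stepFitParams(), spotId = "trace",
                     index = 1L) {
  if (is(y, "BleachTraces")) {
    spotId <- y@spotId[index]
    y <- y@values[index, ]
  }
  stopIfNot(is.numeric(y) && all(is.finite(y)), "trace values must be finite")
  core <- stepFitCore(y, params)
  new("StepFit", spotId = as.character(spotId),
      changePoints = core$changePoints, levels = core$levels,
      nSteps = as.integer(core$nSteps), residualSd = core$residualSd,
      accepted = NA, reason = "unevaluated")
}

acceptCore <- function(nSteps, levels, residualSd, params, background) {
  if (nSteps == 0L) return("no bleaching steps")
  if (nSteps > params$kMax) return("exceeds K_max")
  tol <- 2 * residualSd + 1e-6 * max(abs(levels), 1)
  if (abs(levels[length(levels)] - background) > tol)
    return("did not return to background (incomplete bleaching)")
  d <- abs(diff(levels))
  if (max(d) > params$maxStepRatio * stats::median(d))
    return("oversized step (coincident double bleach suspected)")
  "ok"
}

#' Quality-control a step fit
#'
#' Rejects fits with no steps, more steps than \code{kMax}, traces that do
#' not return to background within twice the residual standard deviation
#' (incomplete bleaching), and fits containing a step larger than
#' \code{maxStepRatio} times the median step magnitude (a coincident
#' double bleach cannot be counted reliably). The reason is recorded.
#'
#' @param fit a \linkS4class{StepFit}.
#' @param params list from \code{\link{stepFitParams}}.
#' @param background expected post-bleach level (0 for background-corrected
#'   traces).
#' @return the \linkS4class{StepFit} with \code{accepted} and \code{reason}
#'   filled in.
#' @export
acceptTrace <- function(fit, params = stepFitParams(), background = 0) {
  reason <- acceptCore(fit@nSteps, fit@levels, fit@residualSd, params,
                       background)
  initialize(fit, accepted = reason == "ok", reason = reason)
}

#' Fit and quality-control every trace in a set
#'
#' Vectorised batch path over a \linkS4class{BleachTraces}; equivalent to
#' \code{\link{fitSteps}} + \code{\link{acceptTrace}} per trace.
#'
#' @param traces a \linkS4class{BleachTraces}.
#' @param params list from \code{\link{stepFitParams}}.
#' @param background expected post-bleach level.
#' @return data.frame with columns spotId, nSteps, residualSd, accepted,
#'   reason.
#' @export
countSteps <- function(traces, params = stepFitParams(), background = 0) {
  v <- traces@values
  n <- nrow(v)
  nSteps <- integer(n); resSd <- numeric(n); reason <- character(n)
  for (i in seq_len(n)) {
    core <- stepFitCore(v[i, ], params)
    nSteps[i] <- core$nSteps
    resSd[i] <- core$residualSd
    reason[i] <- acceptCore(core$nSteps, core$levels, core$residualSd,
                            params, background)
  }
  data.frame(spotId = traces@spotId, nSteps = nSteps, residualSd = resSd,
             accepted = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Tabulate the step-count frequency distribution
#'
#' Counts accepted fits by their number of steps, k = 1..kMax: the
#' observed frequency distribution that the stoichiometry model is fitted
#' to.
#'
#' @param fits a data.frame from \code{\link{countSteps}}, or a list of
#'   quality-controlled \linkS4class{StepFit} objects.
#' @param kMax largest step count tabulated.
#' @return a \linkS4class{StepCountTable}.
#' @examples
#' fits <- data.frame(nSteps = c(1, 2, 2, 1), accepted = TRUE)
#' countDistribution(fits)
#' @export
countDistribution <- function(fits, kMax = 4L) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- data.frame(
      nSteps = vapply(fits, function(f) f@nSteps, 0L),
      accepted = vapply(fits, function(f) isTRUE(f@accepted), logical(1)))
  }
  k <- fits$nSteps[fits$accepted]
  if (!length(k)) stop("no accepted fits to tabulate", call. = FALSE)
  stopIfNot(all(k >= 1L & k <= kMax), "accepted step counts outside 1..kMax")
  counts <- stats::setNames(as.integer(tabulate(k, nbins = kMax)),
                            as.character(seq_len(kMax)))
  new("StepCountTable", counts = counts,
      totalSpots = length(k), kMax = as.integer(kMax))
}

#' Build a StepCountTable directly from counts
#'
#' @param counts named ("1".."K") or positional integer vector of spot
#'   counts per step number.
#' @param kMax largest step count; defaults to the highest named/indexed k.
#' @return a \linkS4class{StepCountTable}.
#' @examples
#' stepCountTable(c(`1` = 248, `2` = 252))
#' @export
stepCountTable <- function(counts, kMax = NULL) {
  ks <- if (is.null(names(counts))) seq_along(counts)
        else as.integer(names(counts))
  if (is.null(kMax)) kMax <- max(ks)
  full <- integer(kMax)
  full[ks] <- as.integer(counts)
  names(full) <- as.character(seq_len(kMax))
  new("StepCountTable", counts = full, totalSpots = sum(full),
      kMax = as.integer(kMax))
}
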