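#' @include AllClasses.R utils.R
NULL

roiMean <- function(img, mask) mean(img[as.logical(mask)])

#' Acceptor bleach depth
#'
#' Fraction of acceptor intensity destroyed inside the bleached ROI:
#' \eqn{\beta = 1 - \bar A_{post} / \bar A_{pre}}, clipped to [0, 1] with a
#' warning when clipping occurs. A good acceptor-photobleaching experiment
#' reaches a depth of roughly 0.8.
#'
#' @param set a \linkS4class{FretImageSet}.
#' @return beta in [0, 1].
#' @examples
#' fs <- simulateFretPair(eTrue = 0.2, bleachDepthTrue = 0.8)
#' acceptorBleachDepth(fs)
#' @export
acceptorBleachDepth <- function(set) {
  validObject(set)
  pre <- roiMean(set@acceptorPre, set@bleachRoi)
  stopIfNot(pre > 0, "zero pre-bleach acceptor signal in the bleach ROI")
  beta <- 1 - roiMean(set@acceptorPost, set@bleachRoi) / pre
  if (beta < 0 || beta > 1) {
    warning("bleach depth ", signif(beta, 4), " clipped to [0, 1]")
    beta <- min(max(beta, 0), 1)
  }
  beta
}

#' Scan-loss correction factor
#'
#' Donor intensity ratio post/pre in the unbleached control region of the
#' cell: the whole-scan fluorescence loss that affects the donor
#' irrespective of acceptor bleaching. The corrected post-bleach donor is
#' \code{fAfterRaw / rho}.
#'
#' @param set a \linkS4class{FretImageSet}.
#' @return rho > 0.
#' @export
scanCorrectionFactor <- function(set) {
  validObject(set)
  pre <- roiMean(set@donorPre, set@controlRoi)
  stopIfNot(pre > 0, "zero donor signal in the control ROI")
  rho <- roiMean(set@donorPost, set@controlRoi) / pre
  stopIfNot(rho > 0, "non-positive scan correction factor")
  rho
}

#' Acceptor-photobleaching FRET efficiency for one cell
#'
#' Computes the apparent FRET efficiency from donor dequenching:
#' \deqn{E_{app} = 100 (F_{after} - F_{before}) / F_{before}}
#' where both intensities are ROI pixel means of the donor in the bleached
#' region and \eqn{F_{after}} has been divided by the control-region scan
#' factor. The conventional normalisation
#' \eqn{100 (F_{after} - F_{before}) / F_{after}} is reported alongside as
#' \code{efficiencyCanonicalPct}. Quality control passes when the acceptor
#' bleach depth reaches \code{qcMinBleach}.
#'
#' @param set a \linkS4class{FretImageSet}.
#' @param qcMinBleach minimum acceptor bleach depth for QC (default 0.7,
#'   an operationalisation of the ~80\% depth a good experiment reaches).
#' @return a \linkS4class{FretResult}.
#' @examples
#' fs <- simulateFretPair(eTrue = 0.2, bleachDepthTrue = 0.8)
#' computeFretEfficiency(fs)   # 100 * 0.8 * 0.2 / 0.8 = 20%
#' @export
computeFretEfficiency <- function(set, qcMinBleach = 0.7) {
  validObject(set)
  fBefore <- roiMean(set@donorPre, set@bleachRoi)
  stopIfNot(fBefore > 0, "non-positive pre-bleach donor intensity")
  fAfterRaw <- roiMean(set@donorPost, set@bleachRoi)
  rho <- scanCorrectionFactor(set)
  fAfter <- fAfterRaw / rho
  beta <- acceptorBleachDepth(set)
  new("FretResult", cellId = set@cellId, fBefore = fBefore,
      fAfterRaw = fAfterRaw, scanFactor = rho, fAfterCorrected = fAfter,
      efficiencyPct = 100 * (fAfter - fBefore) / fBefore,
      efficiencyCanonicalPct = 100 * (fAfter - fBefore) / fAfter,
      bleachDepth = beta, passedQc = beta >= qcMinBleach)
}

#' Summarise FRET efficiencies over a group of cells
#'
#' Plain mean and standard error over the QC-passing cells of one
#' experimental group.
#'
#' @param results list of \linkS4class{FretResult} objects, or a numeric
#'   vector of efficiencies.
#' @param label group label.
#' @param qcOnly when results are \linkS4class{FretResult}s, use only
#'   QC-passing cells.
#' @return data.frame with columns label, mean, sem, n (sem is NA for a
#'   single cell).
#' @examples
#' summarizeGroup(c(10, 20, 30), "demo")
#' @export
summarizeGroup <- function(results, label = "group", qcOnly = TRUE) {
  if (is.list(results)) {
    eff <- vapply(results, function(r) r@efficiencyPct, 0)
    if (qcOnly) eff <- eff[vapply(results, function(r) r@passedQc, logical(1))]
  } else eff <- as.numeric(results)
  stopIfNot(length(eff) >= 1, "no QC-passing results to summarise")
  data.frame(label = label, mean = mean(eff),
             sem = if (length(eff) > 1) stats::sd(eff) / sqrt(length(eff))
                   else NA_real_,
             n = length(eff), stringsAsFactors = FALSE)
}
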