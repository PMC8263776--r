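#' @include utils.R
NULL

# default side-by-side square ROIs for simulated FRET cells
defaultFretRois <- function(shape) {
  H <- shape[1]; W <- shape[2]
  bleach <- matrix(FALSE, H, W)
  control <- matrix(FALSE, H, W)
  qh <- floor(H / 4); qw <- floor(W / 4)
  bleach[qh:(2 * qh), qw:(2 * qw - 1)] <- TRUE
  control[qh:(2 * qh), (W - 2 * qw + 1):(W - qw)] <- TRUE
  list(bleach = bleach, control = control)
}

#' Simulate an acceptor-photobleaching FRET image set
#'
#' Generates the four images of one acceptor-photobleaching experiment
#' under the standard dequenching model. With donor unquenched intensity
#' \eqn{D}, true transfer efficiency \eqn{E}, acceptor bleach depth
#' \eqn{\beta} and per-acquisition scan loss \eqn{s}:
#' pre-bleach donor is \eqn{D (1 - E)} everywhere; post-bleach donor inside
#' the bleached ROI is \eqn{D (1 - E (1 - \beta)) (1 - s)} and outside it
#' \eqn{D (1 - E)(1 - s)}; the acceptor loses the fraction \eqn{\beta}
#' inside the ROI only. The noiseless pipeline estimate of the apparent
#' efficiency is therefore \eqn{100 \beta E / (1 - E)} percent.
#'
#' @param eTrue true FRET efficiency, fraction in [0, 1).
#' @param bleachDepthTrue acceptor bleach depth beta in [0, 1]; the
#'   experimental benchmark is roughly 0.8.
#' @param scanLossTrue fractional donor loss per acquisition scan in [0, 1).
#' @param donorUnquenched unquenched donor intensity, a.u.
#' @param acceptorLevel acceptor intensity, a.u.
#' @param shape image shape (rows, cols).
#' @param bleachRoi,controlRoi logical masks; defaults are two disjoint
#'   square ROIs.
#' @param noiseSd additive Gaussian pixel noise s.d., a.u.
#' @param seed integer seed.
#' @param cellId identifier.
#' @return a \linkS4class{FretImageSet}.
#' @examples
#' fs <- simulateFretPair(eTrue = 0.2, bleachDepthTrue = 0.8)
#' computeFretEfficiency(fs)
#' @export
simulateFretPair <- function(eTrue, bleachDepthTrue = 0.8, scanLossTrue = 0,
                             donorUnquenched = 100, acceptorLevel = 100,
                             shape = c(64L, 64L), bleachRoi = NULL,
                             controlRoi = NULL, noiseSd = 0, seed = 1L,
                             cellId = "cell1") {
  stopIfNot(is.finite(eTrue) && eTrue >= 0 && eTrue < 1,
            "'eTrue' must lie in [0, 1): total transfer is unphysical")
  stopIfNot(bleachDepthTrue >= 0 && bleachDepthTrue <= 1,
            "'bleachDepthTrue' must lie in [0, 1]")
  stopIfNot(scanLossTrue >= 0 && scanLossTrue < 1,
            "'scanLossTrue' must lie in [0, 1)")
  stopIfNot(donorUnquenched > 0, "'donorUnquenched' must be positive")
  if (is.null(bleachRoi) || is.null(controlRoi)) {
    rois <- defaultFretRois(shape)
    if (is.null(bleachRoi)) bleachRoi <- rois$bleach
    if (is.null(controlRoi)) controlRoi <- rois$control
  }
  H <- nrow(bleachRoi); W <- ncol(bleachRoi)
  quenched <- donorUnquenched * (1 - eTrue)
  donorPre <- matrix(quenched, H, W)
  donorPost <- matrix(quenched * (1 - scanLossTrue), H, W)
  donorPost[bleachRoi] <- donorUnquenched *
    (1 - eTrue * (1 - bleachDepthTrue)) * (1 - scanLossTrue)
  acceptorPre <- matrix(acceptorLevel, H, W)
  acceptorPost <- acceptorPre
  acceptorPost[bleachRoi] <- acceptorLevel * (1 - bleachDepthTrue)
  if (noiseSd > 0) {
    imgs <- withSeed(derivedSeed(seed, "fret"), {
      lapply(list(donorPre, donorPost, acceptorPre, acceptorPost), function(m)
        m + matrix(stats::rnorm(length(m), sd = noiseSd), H, W))
    })
    donorPre <- imgs[[1]]; donorPost <- imgs[[2]]
    acceptorPre <- imgs[[3]]; acceptorPost <- imgs[[4]]
  }
  new("FretImageSet", donorPre = donorPre, donorPost = donorPost,
      acceptorPre = acceptorPre, acceptorPost = acceptorPost,
      bleachRoi = bleachRoi, controlRoi = controlRoi, cellId = cellId)
}
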