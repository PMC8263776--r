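#' @include AllClasses.R utils.R
NULL

#' Spot-detection parameters
#'
#' @param psfSigma expected PSF sigma in pixels (matched-filter width).
#' @param kSigma detection threshold in robust s.d. units of the filtered
#'   mean image.
#' @param relMin candidate peaks must also exceed this fraction of the
#'   brightest filtered peak (suppresses numerically tiny maxima in
#'   noise-free images).
#' @param roiSize ROI side length in pixels (the summed-ROI convention is
#'   6 x 6).
#' @param meanFrames number of initial frames averaged for detection
#'   (early frames, before most fluorophores have bleached).
#' @param immobilityRadius maximum allowed centroid excursion from the mean
#'   centroid over a spot's visible lifetime, pixels.
#' @return a named list of parameters.
#' @export
spotDetectParams <- function(psfSigma = 1.2, kSigma = 5, relMin = 0.05,
                             roiSize = 6L, meanFrames = 10L,
                             immobilityRadius = 1.0) {
  stopIfNot(roiSize >= 3L, "'roiSize' must be at least 3")
  list(psfSigma = psfSigma, kSigma = kSigma, relMin = relMin,
       roiSize = as.integer(roiSize), meanFrames = as.integer(meanFrames),
       immobilityRadius = immobilityRadius)
}

# ROI row/col index span for a centre pixel: the centre sits mid-block for
# odd sizes and at the upper-left of the central 2x2 for even sizes
roiSpan <- function(center, size) {
  lo <- center - ceiling(size / 2) + 1L
  seq.int(lo, lo + size - 1L)
}

#' Detect immobile diffraction-limited spots in a movie
#'
#' Candidates come from a matched-filter (Gaussian of the PSF width) pass
#' on the temporal mean of the early frames followed by strict 8-neighbour
#' local-maximum selection above a robust threshold. Overlapping candidate
#' ROIs are resolved by keeping the brighter (ties broken by row, then
#' column). Each surviving candidate must pass the immobility criterion:
#' the intensity-weighted centroid, tracked over the frames in which the
#' spot is visibly above background, may not stray more than
#' \code{immobilityRadius} pixels from its mean.
#'
#' An empty result is valid (a blank movie yields zero ROIs).
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param params list from \code{\link{spotDetectParams}}.
#' @return data.frame with columns spotId, row, col, size, peak (filtered
#'   peak height).
#' @export
detectImmobileSpots <- function(movie, params = spotDetectParams()) {
  validObject(movie)
  d <- movie@data
  nF <- dim(d)[1]; H <- dim(d)[2]; W <- dim(d)[3]
  sz <- params$roiSize
  nUse <- min(params$meanFrames, nF)
  mi <- colMeans(d[seq_len(nUse), , , drop = FALSE], dims = 1)
  bg0 <- stats::median(mi)
  f <- sepGaussFilter(mi - bg0, params$psfSigma)
  sigmaF <- stats::mad(f)
  thr <- max(params$kSigma * sigmaF, params$relMin * max(f), 0)

  # strict local maxima over the 8-neighbourhood, away from the border
  isMax <- matrix(FALSE, H, W)
  core <- f[2:(H - 1), 2:(W - 1)]
  cond <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cond <- cond & (core > f[2:(H - 1) + dr, 2:(W - 1) + dc])
  }
  isMax[2:(H - 1), 2:(W - 1)] <- cond
  cand <- which(isMax, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(spotId = character(0), row = integer(0),
                      col = integer(0), size = integer(0), peak = numeric(0)))
  }
  peak <- f[cand]
  ord <- order(-peak, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  peak <- peak[ord]

  # keep ROIs fully inside the image and pairwise non-overlapping
  keep <- logical(nrow(cand))
  taken <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(cand))) {
    rows <- roiSpan(cand[i, 1], sz); cols <- roiSpan(cand[i, 2], sz)
    if (rows[1] < 1 || cols[1] < 1 || rows[sz] > H || cols[sz] > W) next
    if (any(taken[rows, cols])) next
    keep[i] <- TRUE
    taken[rows, cols] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  peak <- peak[keep]
  if (!nrow(cand)) {
    return(data.frame(spotId = character(0), row = integer(0),
                      col = integer(0), size = integer(0), peak = numeric(0)))
  }

  pixNoise <- estimatePixelNoise(movie)
  immobile <- vapply(seq_len(nrow(cand)), function(i) {
    rows <- roiSpan(cand[i, 1], sz); cols <- roiSpan(cand[i, 2], sz)
    block <- d[, rows, cols, drop = FALSE]
    w <- pmax(block - bg0, 0)
    s <- rowSums(w, dims = 1)
    visThr <- max(3 * pixNoise * sz, 0.2 * max(s), 1e-12)
    vis <- which(s > visThr)
    if (!length(vis)) return(FALSE)
    cr <- vapply(vis, function(fr) sum(w[fr, , ] * rows) / s[fr], 0)
    cc <- vapply(vis, function(fr) {
      sum(sweep(w[fr, , , drop = TRUE], 2, cols, "*")) / s[fr]
    }, 0)
    exc <- sqrt((cr - mean(cr))^2 + (cc - mean(cc))^2)
    max(exc) <= params$immobilityRadius
  }, logical(1))
  cand <- cand[immobile, , drop = FALSE]
  peak <- peak[immobile]
  data.frame(spotId = sprintf("roi%04d", seq_len(nrow(cand))),
             row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
             size = rep(sz, nrow(cand)), peak = peak,
             stringsAsFactors = FALSE)
}

#' Estimate per-frame background from off-spot pixels
#'
#' Per-frame median over all pixels outside every ROI footprint, per unit
#' pixel; multiply by the ROI pixel count when subtracting from a summed
#' trace. Falls back (with a warning) to the global per-frame median when
#' the ROIs cover the whole image.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param rois data.frame with columns row, col, size (as returned by
#'   \code{\link{detectImmobileSpots}}), or NULL for no exclusions.
#' @return numeric vector, one background value per frame (a.u. per pixel).
#' @export
estimateBackground <- function(movie, rois = NULL) {
  validObject(movie)
  d <- movie@data
  nF <- dim(d)[1]; H <- dim(d)[2]; W <- dim(d)[3]
  outside <- matrix(TRUE, H, W)
  if (!is.null(rois) && nrow(rois)) {
    for (i in seq_len(nrow(rois))) {
      outside[roiSpan(rois$row[i], rois$size[i]),
              roiSpan(rois$col[i], rois$size[i])] <- FALSE
    }
  }
  if (!any(outside)) {
    warning("ROIs cover the whole image; falling back to the global per-frame median")
    outside[] <- TRUE
  }
  vapply(seq_len(nF), function(f) stats::median(d[f, , ][outside]), 0)
}

#' Extract summed-ROI bleaching traces
#'
#' For each ROI, sums the size x size pixel block in every frame and
#' subtracts the per-frame background scaled to the ROI area. Extraction is
#' linear in the movie: the trace of a sum of movies equals the sum of the
#' traces (at zero background).
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param rois data.frame with columns row, col, size (and optionally
#'   spotId).
#' @param background per-frame background per unit pixel (recycled scalar
#'   allowed); defaults to \code{\link{estimateBackground}}.
#' @return a \linkS4class{BleachTraces} with one trace per ROI.
#' @export
extractTraces <- function(movie, rois, background = NULL) {
  validObject(movie)
  d <- movie@data
  nF <- dim(d)[1]; H <- dim(d)[2]; W <- dim(d)[3]
  if (is.null(background)) background <- estimateBackground(movie, rois)
  background <- rep_len(background, nF)
  vals <- matrix(0, nrow(rois), nF)
  for (i in seq_len(nrow(rois))) {
    rows <- roiSpan(rois$row[i], rois$size[i])
    cols <- roiSpan(rois$col[i], rois$size[i])
    stopIfNot(rows[1] >= 1 && cols[1] >= 1 && max(rows) <= H && max(cols) <= W,
              sprintf("ROI %d lies outside the image", i))
    vals[i, ] <- rowSums(d[, rows, cols, drop = FALSE], dims = 1) -
      background * rois$size[i]^2
  }
  ids <- if ("spotId" %in% names(rois)) as.character(rois$spotId)
         else sprintf("roi%04d", seq_len(nrow(rois)))
  new("BleachTraces", values = vals, spotId = ids,
      frameInterval = movie@frameInterval,
      background = vapply(seq_len(nrow(rois)),
                          function(i) mean(background) * rois$size[i]^2, 0))
}

#' @rdname extractTraces
#' @param row,col,size centre pixel and side length of a single ROI.
#' @export
extractTrace <- function(movie, row, col, size = 6L, background = 0) {
  extractTraces(movie,
                data.frame(row = row, col = col, size = as.integer(size)),
                background = background)
}
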