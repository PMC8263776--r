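#' @include AllClasses.R utils.R
NULL

# per-channel threshold within the cell mask
colocThreshold <- function(img, mask, method, fixed = 0) {
  v <- img[mask]
  switch(method,
    zero = 0,
    fixed = fixed,
    otsu = {
      rng <- range(v)
      if (diff(rng) <= 0) return(rng[1])
      # EBImage's Otsu works on [0, 1]; rescale and map the cut back
      sc <- (v - rng[1]) / diff(rng)
      th <- EBImage::otsu(matrix(sc, nrow = 1), range = c(0, 1))
      rng[1] + th * diff(rng)
    },
    stop("unknown threshold method: ", method, call. = FALSE))
}

#' Mander's colocalization coefficients
#'
#' Pixel-by-pixel colocalization of two channels within the cell mask.
#' M1 is the fraction of channel-A intensity falling on pixels where
#' channel B exceeds its threshold; M2 is the converse. The normalized
#' intensity-product overlap coefficient
#' \eqn{R = \sum A_i B_i / \sqrt{\sum A_i^2 \sum B_i^2}} is reported as a
#' secondary output. Swapping the channel roles swaps M1 and M2 exactly,
#' and both coefficients are invariant to a positive rescaling of the
#' non-thresholded channel.
#'
#' @param set a \linkS4class{ColocImageSet}.
#' @param chA,chB channel names in \code{set}.
#' @param method threshold method: "otsu" (within-mask Otsu, default),
#'   "zero", or "fixed".
#' @param fixedThresholds named numeric per-channel thresholds for
#'   \code{method = "fixed"}.
#' @return a \linkS4class{ColocResult}.
#' @examples
#' m <- matrix(c(10, 0, 5, 0), 2)
#' b <- matrix(c(0, 0, 3, 7), 2)
#' set <- new("ColocImageSet", channels = list(A = m, B = b),
#'            cellMask = matrix(TRUE, 2, 2), acquisition = list(),
#'            cellId = "demo")
#' mandersCoefficients(set, "A", "B", method = "zero")  # M1 = 1/3, M2 = 0.3
#' @export
mandersCoefficients <- function(set, chA, chB, method = "otsu",
                                fixedThresholds = c(A = 0, B = 0)) {
  validObject(set)
  stopIfNot(all(c(chA, chB) %in% names(set@channels)),
            "requested channels not present in the image set")
  mask <- as.logical(set@cellMask)
  A <- set@channels[[chA]][mask]
  B <- set@channels[[chB]][mask]
  stopIfNot(sum(A) > 0 && sum(B) > 0,
            "zero total intensity in a channel within the cell mask")
  thA <- colocThreshold(set@channels[[chA]], mask, method,
                        fixed = unname(fixedThresholds[1]))
  thB <- colocThreshold(set@channels[[chB]], mask, method,
                        fixed = unname(fixedThresholds[2]))
  m1 <- sum(A[B > thB]) / sum(A)
  m2 <- sum(B[A > thA]) / sum(B)
  overlap <- sum(A * B) / sqrt(sum(A^2) * sum(B^2))
  th <- c(thA, thB); names(th) <- c(chA, chB)
  new("ColocResult", cellId = set@cellId, m1 = m1, m2 = m2,
      overlapR = overlap, thresholds = th, thresholdMethod = method)
}

#' Per-cell expression ratio versus ER colocalization
#'
#' For every cell: x = mean regulator intensity / mean reporter intensity
#' within the cell mask (the regulator/reporter expression ratio), and
#' y = M1 of the reporter against the ER channel (the fraction of reporter
#' intensity on ER-positive pixels). Requires all three channels and,
#' because the ratio is only meaningful when images share acquisition
#' settings, rejects batches whose recorded acquisition metadata differ.
#'
#' @param sets list of \linkS4class{ColocImageSet} with channels
#'   \code{reporter}, \code{er} and \code{regulator}.
#' @param method threshold method passed to
#'   \code{\link{mandersCoefficients}}.
#' @return data.frame with columns cellId, ratio, erColoc.
#' @examples
#' pan <- simulateColocPanel(ratios = c(0, 1, 2), seed = 4)
#' perCellRatioAnalysis(pan$sets)
#' @export
perCellRatioAnalysis <- function(sets, method = "otsu") {
  stopIfNot(length(sets) >= 1, "no cells supplied")
  need <- c("reporter", "er", "regulator")
  for (s in sets)
    stopIfNot(all(need %in% names(s@channels)),
              "each cell needs reporter, er and regulator channels")
  acq <- lapply(sets, function(s) s@acquisition)
  if (length(unique(acq)) != 1L)
    stop("acquisition settings differ across cells; ",
         "ratios are only comparable at matched settings", call. = FALSE)
  out <- lapply(sets, function(s) {
    mask <- as.logical(s@cellMask)
    ratio <- mean(s@channels$regulator[mask]) / mean(s@channels$reporter[mask])
    cr <- mandersCoefficients(s, "reporter", "er", method = method)
    data.frame(cellId = s@cellId, ratio = ratio, erColoc = cr@m1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

decaySse <- function(par, x, y) sum((y - (par[1] * exp(-par[2] * x) + par[3]))^2)

#' Fit an exponential decay to colocalization-versus-ratio points
#'
#' Bounded nonlinear least squares for \eqn{y = A e^{-k x} + C} with
#' \eqn{A, k \ge 0} and \eqn{C \in [0, 1]}, using five deterministic
#' data-derived starting points and returning the best-SSE solution.
#' Degenerate inputs (constant y) return a flat fit with \code{rate = 0}
#' and \code{rSquared = 0}, flagged.
#'
#' @param points data.frame with columns x (>= 0) and y.
#' @param fixC hold the offset at zero.
#' @return a \linkS4class{DecayFit}.
#' @examples
#' x <- seq(0, 2, 0.25)
#' fitExponentialDecay(data.frame(x = x, y = 0.9 * exp(-1.5 * x)))
#' @export
fitExponentialDecay <- function(points, fixC = FALSE) {
  x <- points$x; y <- points$y
  stopIfNot(length(x) >= 4, "need at least 4 points")
  stopIfNot(all(is.finite(x)) && all(is.finite(y)), "points must be finite")
  stopIfNot(all(x >= 0), "x must be non-negative")
  stopIfNot(stats::sd(x) > 0, "degenerate x: all values equal")
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) {
    return(new("DecayFit", amplitude = 0, rate = 0,
               offset = if (fixC) 0 else min(max(mean(y), 0), 1),
               rSquared = 0, sse = 0, nCells = length(x), flat = TRUE))
  }
  span <- max(diff(range(y)), 1e-6)
  xspan <- max(diff(range(x)), 1e-6)
  starts <- list(
    c(A = span, k = 1 / xspan, C = max(min(y), 0)),
    c(A = span, k = 4 / xspan, C = max(min(y), 0)),
    c(A = span / 2, k = 0.5 / xspan, C = max(min(y), 0)),
    c(A = max(y[which.min(x)], 0.1), k = 2 / xspan, C = 0),
    c(A = 0.5, k = 1, C = 0.1)
  )
  lower <- c(0, 0, 0); upper <- c(Inf, Inf, 1)
  if (fixC) upper[3] <- 0
  best <- NULL
  for (st in starts) {
    if (fixC) st["C"] <- 0
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-k * x) + C,
                        data = data.frame(x = x, y = y),
                        start = as.list(st), lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(par = stats::coef(fit), sse = sse)
  }
  stopIfNot(!is.null(best), "decay fit failed from every starting point")
  p <- best$par
  flat <- p[["A"]] < 1e-8 || p[["k"]] < 1e-8
  new("DecayFit", amplitude = p[["A"]], rate = p[["k"]], offset = p[["C"]],
      rSquared = 1 - best$sse / ssTot, sse = best$sse,
      nCells = length(x), flat = flat)
}
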