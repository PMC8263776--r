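#' @include utils.R
NULL

#' Standard cell geometry for simulated colocalization panels
#'
#' A circular cell footprint with a central ER region and a peripheral
#' membrane ring, mutually disjoint.
#'
#' @param shape image shape (rows, cols).
#' @return list of logical masks \code{cell}, \code{er}, \code{mb}.
#' @export
colocCellGeometry <- function(shape = c(64L, 64L)) {
  H <- shape[1]; W <- shape[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  rr <- outer(seq_len(H), rep(1, W)) - ctr[1]
  cc <- outer(rep(1, H), seq_len(W)) - ctr[2]
  d <- sqrt(rr^2 + cc^2)
  rCell <- 0.44 * min(H, W)
  list(cell = d <= rCell,
       er = d <= 0.42 * rCell,
       mb = d > 0.85 * rCell & d <= rCell)
}

#' Simulate one cell of a colocalization panel
#'
#' The reporter's total intensity is split between the ER mask and the
#' membrane mask according to the ER fraction
#' \eqn{f = A e^{-k \cdot ratio} + C}, where \code{ratio} is the
#' regulator/reporter expression ratio; the regulator fills the cell
#' footprint uniformly and the ER marker labels the ER mask. Noiselessly,
#' ER-mask intensity plus membrane-mask intensity equals the total reporter
#' intensity exactly.
#'
#' @param ratio regulator/reporter expression ratio (x of the decay curve).
#' @param A,k,C decay amplitude, rate and offset; \code{A + C} must not
#'   exceed 1 so the ER fraction stays a fraction.
#' @param reporterLevel mean reporter intensity over the cell mask, a.u.
#' @param erMarkerLevel ER-marker intensity on the ER mask, a.u.
#' @param geometry masks from \code{\link{colocCellGeometry}}.
#' @param noiseSd additive Gaussian pixel noise s.d., a.u. (negative pixel
#'   values are clipped to zero).
#' @param seed integer seed.
#' @param cellId identifier.
#' @param acquisition named list of acquisition settings recorded in the
#'   image set; batch analyses check these match across cells.
#' @return list with \code{set} (a \linkS4class{ColocImageSet}) and
#'   \code{erFractionTrue}.
#' @export
simulateColocCell <- function(ratio, A = 0.9, k = 1.5, C = 0,
                              reporterLevel = 100, erMarkerLevel = 100,
                              geometry = colocCellGeometry(),
                              noiseSd = 0, seed = 1L, cellId = "cell1",
                              acquisition = list(laser = 1, gain = 1)) {
  stopIfNot(A >= 0 && k >= 0, "'A' and 'k' must be non-negative")
  stopIfNot(C >= 0 && C <= 1, "'C' must lie in [0, 1]")
  stopIfNot(A + C <= 1, "A + C must not exceed 1 (the ER fraction is a fraction)")
  stopIfNot(ratio >= 0, "'ratio' must be non-negative")
  cellM <- geometry$cell; erM <- geometry$er; mbM <- geometry$mb
  stopIfNot(any(erM) && any(mbM), "ER and membrane masks must be nonempty")
  stopIfNot(!any(erM & mbM), "ER and membrane masks must be disjoint")
  f <- A * exp(-k * ratio) + C
  total <- reporterLevel * sum(cellM)
  reporter <- matrix(0, nrow(cellM), ncol(cellM))
  reporter[erM] <- f * total / sum(erM)
  reporter[mbM] <- (1 - f) * total / sum(mbM)
  er <- matrix(0, nrow(cellM), ncol(cellM))
  er[erM] <- erMarkerLevel
  regulator <- matrix(0, nrow(cellM), ncol(cellM))
  regulator[cellM] <- ratio * reporterLevel
  chans <- list(reporter = reporter, er = er, regulator = regulator)
  if (noiseSd > 0) {
    chans <- withSeed(derivedSeed(seed, paste0("coloc-", cellId)), {
      lapply(chans, function(m)
        pmax(m + matrix(stats::rnorm(length(m), sd = noiseSd), nrow(m)), 0))
    })
  }
  set <- new("ColocImageSet", channels = chans, cellMask = cellM,
             acquisition = acquisition, cellId = cellId)
  list(set = set, erFractionTrue = f)
}

#' Simulate a colocalization panel across regulator doses
#'
#' One cell per entry of \code{ratios}; cells ordered by increasing ratio
#' have monotonically non-increasing noiseless ER fractions.
#'
#' @inheritParams simulateColocCell
#' @param ratios numeric vector of regulator/reporter ratios, one cell each.
#' @return list with \code{sets} (list of \linkS4class{ColocImageSet}) and
#'   \code{truth} (data.frame cellId, ratio, erFractionTrue).
#' @examples
#' pan <- simulateColocPanel(ratios = c(0, 0.5, 1, 2), seed = 5)
#' pan$truth
#' @export
simulateColocPanel <- function(ratios, A = 0.9, k = 1.5, C = 0,
                               reporterLevel = 100, erMarkerLevel = 100,
                               geometry = colocCellGeometry(),
                               noiseSd = 0, seed = 1L) {
  ids <- sprintf("cell%03d", seq_along(ratios))
  sims <- lapply(seq_along(ratios), function(i)
    simulateColocCell(ratios[i], A = A, k = k, C = C,
                      reporterLevel = reporterLevel,
                      erMarkerLevel = erMarkerLevel, geometry = geometry,
                      noiseSd = noiseSd, seed = seed, cellId = ids[i]))
  list(sets = lapply(sims, `[[`, "set"),
       truth = data.frame(cellId = ids, ratio = ratios,
                          erFractionTrue = vapply(sims, `[[`, 0, "erFractionTrue"),
                          stringsAsFactors = FALSE))
}

#' Simulate per-cell decay observations
#'
#' Point-level generator for the colocalization-versus-ratio analysis: each
#' cell contributes one observation \eqn{y = A e^{-k x} + C + \epsilon}
#' with Gaussian measurement noise on y, clipped to [0, 1] (the observable
#' is a colocalized fraction).
#'
#' @inheritParams simulateColocCell
#' @param ratios numeric vector of x values (regulator/reporter ratios).
#' @param noiseSd s.d. of the y measurement noise.
#' @return data.frame with columns x, y.
#' @export
simulateDecayPoints <- function(ratios, A = 0.9, k = 1.5, C = 0,
                                noiseSd = 0.05, seed = 1L) {
  stopIfNot(all(ratios >= 0), "'ratios' must be non-negative")
  y0 <- A * exp(-k * ratios) + C
  withSeed(derivedSeed(seed, "decay-points"), {
    y <- y0 + stats::rnorm(length(ratios), sd = noiseSd)
    data.frame(x = ratios, y = pmin(pmax(y, 0), 1))
  })
}
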