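#' @include sim-population.R
NULL

# survivors per frame for one spot's bleach-time vector
survivorsOne <- function(times, nFrames, dt) {
  if (!length(times)) return(integer(nFrames))
  idx <- pmin(ceiling(times / dt), nFrames + 1L)
  length(times) - c(0L, cumsum(tabulate(idx, nFrames + 1L)))[seq_len(nFrames)]
}

# pixel-integrated isotropic Gaussian: mass of a unit PSF centred at
# (r0, c0) falling into each pixel of rows x cols (pixel i covers
# [i - 0.5, i + 0.5])
psfStamp <- function(rows, cols, r0, c0, sigma) {
  pr <- stats::pnorm(rows + 0.5, r0, sigma) - stats::pnorm(rows - 0.5, r0, sigma)
  pc <- stats::pnorm(cols + 0.5, c0, sigma) - stats::pnorm(cols - 0.5, c0, sigma)
  outer(pr, pc)
}

#' Render a spot population as a TIRF movie stack
#'
#' Places every surviving fluorophore of every spot as a pixel-integrated
#' isotropic Gaussian of total mass \code{unitIntensity}, adds the constant
#' background, and (optionally) per-pixel noise. With a nonzero
#' \code{driftPerFrame} in the configuration, spots translate linearly
#' frame by frame, which is used to exercise the immobility filter. In the
#' noiseless case the integrated intensity over any spot neighbourhood is
#' weakly decreasing in time.
#'
#' @param truth a \linkS4class{SpotTruth} from
#'   \code{\link{simulateSpotPopulation}}.
#' @param config a \linkS4class{SimConfig}; defaults to the one stored in
#'   \code{truth}.
#' @return a \linkS4class{MovieStack}.
#' @examples
#' cfg <- simConfig(seed = 2, nSpots = 5, nFrames = 20,
#'                  imageShape = c(48L, 48L), noiseSd = 0)
#' mov <- renderMovie(simulateSpotPopulation(cfg)$truth)
#' mov
#' @export
renderMovie <- function(truth, config = simConfigOf(truth)) {
  validObject(config)
  tb <- truth@table
  H <- config@imageShape[1]; W <- config@imageShape[2]
  nF <- config@nFrames
  rad <- ceiling(4 * config@psfSigma)
  arr <- array(config@backgroundLevel, c(nF, H, W))
  drift <- config@driftPerFrame
  static <- all(drift == 0)
  for (i in seq_len(nrow(tb))) {
    if (!tb$visible[i]) next
    surv <- survivorsOne(truth@bleachTimes[[i]], nF, config@frameInterval)
    if (static) {
      rows <- max(1L, floor(tb$row[i]) - rad):min(H, ceiling(tb$row[i]) + rad)
      cols <- max(1L, floor(tb$col[i]) - rad):min(W, ceiling(tb$col[i]) + rad)
      stamp <- config@unitIntensity * psfStamp(rows, cols, tb$row[i], tb$col[i],
                                               config@psfSigma)
      arr[, rows, cols] <- arr[, rows, cols] + outer(surv, stamp)
    } else {
      for (f in which(surv > 0)) {
        r0 <- tb$row[i] + (f - 1) * drift[1]
        c0 <- tb$col[i] + (f - 1) * drift[2]
        rows <- max(1L, floor(r0) - rad):min(H, ceiling(r0) + rad)
        cols <- max(1L, floor(c0) - rad):min(W, ceiling(c0) + rad)
        arr[f, rows, cols] <- arr[f, rows, cols] +
          surv[f] * config@unitIntensity *
          psfStamp(rows, cols, r0, c0, config@psfSigma)
      }
    }
  }
  arr <- withSeed(derivedSeed(config@seed, "movie"), {
    if (config@noiseModel == "poisson") {
      array(stats::rpois(length(arr), pmax(arr, 0)), dim(arr))
    } else if (config@noiseSd > 0) {
      arr + array(stats::rnorm(length(arr), sd = config@noiseSd), dim(arr))
    } else arr
  })
  new("MovieStack", data = arr, frameInterval = config@frameInterval)
}
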