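#' @include AllClasses.R
NULL

# Derive an independent integer seed for a named stochastic stream. Each
# generator draws under its own derived stream so that adding a stage never
# perturbs the draws of another.
derivedSeed <- function(seed, stream) {
  h <- utf8ToInt(stream)
  h <- sum(h * seq_along(h) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Separable Gaussian convolution with replicate padding; kernel normalised
# to unit sum (a matched filter for an isotropic Gaussian PSF).
sepGaussFilter <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# Robust per-pixel noise estimate from the difference of two frames.
estimatePixelNoise <- function(movie) {
  d <- movie@data
  stats::mad(d[2L, , ] - d[1L, , ]) / sqrt(2)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# md5 digests of a set of files, named by basename, in sorted order
fileDigests <- function(paths) {
  paths <- sort(paths)
  md5 <- tools::md5sum(paths)
  stats::setNames(as.character(md5), basename(paths))
}
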