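# Independent oracles used across the suite. These never call the code
# paths they check.

# Detection-conditional step-count distribution by exhaustive enumeration
# of the 2^n on/off subunit configurations, discarding the all-dark one.
enumConditionalPmf <- function(n, p, k) {
  states <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  probs <- apply(states, 1, function(s) prod(ifelse(s == 1, p, 1 - p)))
  lit <- rowSums(states)
  visible <- lit >= 1
  vapply(k, function(kk) sum(probs[visible & lit == kk]) / sum(probs[visible]), 0)
}

# Dense grid-search maximum-likelihood estimate of p for a fixed n.
gridFitP <- function(counts, n, step = 1e-4) {
  grid <- seq(step, 1, by = step)
  ks <- seq_len(min(n, length(counts)))
  ll <- vapply(grid, function(p) {
    pmf <- dbinom(ks, n, p) / (1 - (1 - p)^n)
    use <- counts[ks] > 0
    sum(counts[ks][use] * log(pmf[use]))
  }, 0)
  grid[which.max(ll)]
}

# Grid-search SSE floor for the exponential-decay model.
gridDecaySSE <- function(x, y, nGrid = 50) {
  As <- seq(0, 1, length.out = nGrid)
  ks <- seq(0, 5, length.out = nGrid)
  Cs <- seq(0, 1, length.out = nGrid)
  best <- Inf
  E <- exp(-outer(ks, x))                 # nGrid x length(x)
  for (ai in As) {
    M <- ai * E                           # nGrid x n
    for (ci in Cs) {
      sse <- rowSums((sweep(M, 2, y - ci, FUN = function(a, b) a - b))^2)
      best <- min(best, min(sse))
    }
  }
  best
}

# Euclidean nearest-truth distance for each detected spot.
matchDistances <- function(rois, truthTable) {
  vapply(seq_len(nrow(rois)), function(i) {
    min(sqrt((truthTable$row - rois$row[i])^2 +
             (truthTable$col - rois$col[i])^2))
  }, 0)
}

# Visible-spot pipeline for stoichiometry recovery at a target number of
# visible spots.
runCountingRecovery <- function(seed, n, p = 0.67, nVisible = 1000) {
  nSpots <- round(nVisible / (1 - (1 - p)^n))
  cfg <- simConfig(seed = seed, nSubunits = n, pFluor = p, nSpots = nSpots,
                   imageShape = c(1024L, 1024L), noiseSd = 0)
  sim <- simulateSpotPopulation(cfg)
  tab <- countDistribution(countSteps(sim$traces))
  sel <- selectStoichiometry(tab)
  list(selectedN = selectedN(sel),
       pHat = sel@fits[[paste0("n", n)]]@pHat,
       table = tab)
}
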