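#' @include AllClasses.R step-detection.R
NULL

#' Detection-conditional binomial step-count distribution
#'
#' Probability that a visible complex of \code{n} subunits shows exactly
#' \code{k} bleaching steps when each subunit carries a fluorescent tag
#' independently with probability \code{p}. Because an all-dark complex is
#' invisible, the binomial distribution is conditioned on at least one
#' fluorescent subunit:
#' \deqn{P(k) = \binom{n}{k} p^k (1-p)^{n-k} / (1 - (1-p)^n), k = 1..n.}
#'
#' @param n subunit count (integer >= 1).
#' @param p per-subunit fluorescence probability in (0, 1].
#' @param k number of observed steps, in 1..n (vectorised).
#' @return probabilities in (0, 1], summing to 1 over k = 1..n.
#' @examples
#' conditionalBinomialPmf(4, 0.67, 1:4)
#' sum(conditionalBinomialPmf(4, 0.67, 1:4))
#' @export
conditionalBinomialPmf <- function(n, p, k) {
  stopIfNot(length(n) == 1 && n >= 1 && n == round(n),
            "'n' must be a single integer >= 1")
  stopIfNot(length(p) == 1 && is.finite(p) && p > 0 && p <= 1,
            "'p' must lie in (0, 1] (p = 0 leaves nothing visible)")
  stopIfNot(all(k >= 1 & k <= n & k == round(k)),
            "'k' must be an integer in 1..n")
  stats::dbinom(k, n, p) / (1 - (1 - p)^n)
}

condLogLik <- function(counts, n, p) {
  ks <- seq_len(min(n, length(counts)))
  use <- counts[ks] > 0
  if (!any(use)) return(0)
  sum(counts[ks][use] * log(conditionalBinomialPmf(n, p, ks[use])))
}

#' Fit the per-subunit fluorescence probability for a fixed subunit count
#'
#' Maximises the multinomial log-likelihood of an observed step-count
#' table under the detection-conditional binomial model with \code{n}
#' subunits, over p in (0, 1]. Attaches a 95\% profile-likelihood interval,
#' the expected relative frequencies, and a Pearson chi-square lack-of-fit
#' statistic. For \code{n = 1} the conditional model carries no
#' information about p (a visible monomer always shows one step); p is
#' returned as 1 with a flat-likelihood flag. Counts observed at
#' \code{k > n} are impossible under the model: the fit proceeds on the
#' admissible cells and is flagged (and warned) as lack of fit, with
#' \code{logLik = -Inf}.
#'
#' @param table a \linkS4class{StepCountTable}.
#' @param n assumed subunit count.
#' @return a \linkS4class{BinomialFitResult}.
#' @examples
#' tab <- stepCountTable(c(`1` = 667, `2` = 333))
#' fitBinomialP(tab, n = 2)
#' @export
fitBinomialP <- function(table, n) {
  counts <- table@counts
  stopIfNot(sum(counts) > 0, "empty step-count table")
  n <- as.integer(n)
  kMax <- table@kMax
  lackOfFit <- n < kMax && any(counts[(n + 1):kMax] > 0)
  if (lackOfFit)
    warning("counts observed at k > n = ", n,
            ": impossible under the model, fit flagged as lack of fit")
  pmin_ <- 1e-6
  if (n == 1L) {
    pHat <- 1; pCI <- c(pmin_, 1); converged <- TRUE; flat <- TRUE
    ll <- if (lackOfFit) -Inf else 0
  } else {
    flat <- FALSE
    opt <- stats::optimize(function(p) condLogLik(counts, n, p),
                           interval = c(pmin_, 1), maximum = TRUE,
                           tol = 1e-9)
    pHat <- opt$maximum; llMax <- opt$objective
    # the optimum can sit on the p = 1 boundary
    llEnd <- condLogLik(counts, n, 1)
    if (llEnd > llMax) { pHat <- 1; llMax <- llEnd }
    converged <- TRUE
    drop <- stats::qchisq(0.95, 1) / 2
    bound <- function(lo, hi) {
      fn <- function(p) condLogLik(counts, n, p) - (llMax - drop)
      if (fn(lo) > 0) return(lo)
      stats::uniroot(fn, c(lo, hi), tol = 1e-8)$root
    }
    pCI <- c(if (pHat > pmin_) bound(pmin_, pHat) else pmin_,
             if (pHat < 1) bound(1, pHat) else 1)
    pCI <- sort(pCI)
    ll <- if (lackOfFit) -Inf else llMax
  }
  ef <- numeric(kMax)
  ef[seq_len(min(n, kMax))] <- conditionalBinomialPmf(n, pHat,
                                                      seq_len(min(n, kMax)))
  gof <- tryCatch(
    suppressWarnings(goodnessOfFit(table, n = n, p = pHat,
                                   fittedParams = if (n == 1L) 0L else 1L)),
    error = function(e) list(statistic = NA_real_, df = NA_real_))
  new("BinomialFitResult", n = n, pHat = pHat, pCI = pCI, logLik = ll,
      expectedFreqs = ef, chiSquare = gof$statistic, df = gof$df,
      converged = converged, flatLikelihood = flat, lackOfFit = lackOfFit)
}

#' Select the oligomeric state by AIC over candidate subunit counts
#'
#' Fits the detection-conditional binomial model for every candidate n and
#' compares by AIC = 2 * params - 2 * logLik, with one fitted parameter
#' (p) for n >= 2 and none for n = 1. The minimum-AIC candidate wins; ties
#' go to the smaller n (parsimony).
#'
#' @param table a \linkS4class{StepCountTable}.
#' @param candidates integer vector of subunit counts to compare.
#' @return a \linkS4class{ModelSelectionResult}.
#' @examples
#' tab <- stepCountTable(c(`1` = 248, `2` = 252), kMax = 4)
#' selectStoichiometry(tab)
#' @export
selectStoichiometry <- function(table, candidates = 1:4) {
  stopIfNot(sum(table@counts) > 0, "empty step-count table")
  candidates <- sort(as.integer(candidates))
  fits <- suppressWarnings(lapply(candidates, function(n) fitBinomialP(table, n)))
  ll <- vapply(fits, function(f) f@logLik, 0)
  pars <- ifelse(candidates >= 2L, 1, 0)
  aic <- 2 * pars - 2 * ll
  tab <- data.frame(n = candidates,
                    pHat = vapply(fits, function(f) f@pHat, 0),
                    logLik = ll, AIC = aic)
  best <- which(aic <= min(aic) + 1e-9)[1]  # ties to smaller n
  margin <- if (length(aic) > 1) sort(aic[-best])[1] - aic[best] else NA_real_
  new("ModelSelectionResult", table = tab,
      selectedN = candidates[best], selectionMargin = margin,
      fits = stats::setNames(fits, paste0("n", candidates)))
}

#' Fit a mixture of oligomeric states to a step-count table
#'
#' Maximises the multinomial likelihood of a weighted mixture of
#' detection-conditional binomial components sharing one fluorescence
#' probability p, by expectation-maximisation over the weights (and p,
#' unless fixed). Note the structural confounding: from step counts alone,
#' a pure dimer with p < 1 is nearly indistinguishable from a
#' monomer/dimer mixture, because dark-fluorophore dimers contribute
#' one-step spots exactly where monomers do; a message records this
#' caveat on every fit.
#'
#' @param table a \linkS4class{StepCountTable}.
#' @param components integer vector of candidate subunit counts (>= 2 of
#'   them).
#' @param p fixed shared fluorescence probability, or NULL to estimate it.
#' @param maxIter,tol EM iteration controls.
#' @return a \linkS4class{MixtureFitResult}.
#' @examples
#' tab <- stepCountTable(c(`1` = 496, `2` = 504))
#' fitStoichiometryMixture(tab, p = 0.67)
#' @export
fitStoichiometryMixture <- function(table, components = c(1L, 2L), p = NULL,
                                    maxIter = 500L, tol = 1e-10) {
  counts <- table@counts
  stopIfNot(sum(counts) > 0, "empty step-count table")
  stopIfNot(length(components) >= 2, "need at least two mixture components")
  components <- sort(as.integer(components))
  message("note: from step counts alone a pure ", max(components),
          "-mer with p < 1 is confounded with a mixture containing ",
          "smaller oligomers (dark fluorophores mimic them)")
  ks <- seq_len(table@kMax)
  pFixed <- !is.null(p)
  pCur <- if (pFixed) p else 0.67
  w <- rep(1 / length(components), length(components))
  compPmf <- function(pv) {
    vapply(components, function(n) {
      out <- numeric(length(ks))
      kk <- ks[ks <= n]
      out[ks <= n] <- conditionalBinomialPmf(n, pv, kk)
      out
    }, numeric(length(ks)))
  }
  mixLL <- function(w, pv) {
    m <- compPmf(pv) %*% w
    use <- counts > 0
    if (any(use & m[, 1] <= 0)) return(-Inf)
    sum(counts[use] * log(m[use, 1]))
  }
  llOld <- -Inf
  for (iter in seq_len(maxIter)) {
    P <- compPmf(pCur)                       # kMax x nComp
    joint <- sweep(P, 2, w, "*")
    rowTot <- rowSums(joint)
    resp <- joint / ifelse(rowTot > 0, rowTot, 1)
    w <- colSums(resp * counts) / sum(counts)
    w <- pmax(w, 0); w <- w / sum(w)
    if (!pFixed) {
      obj <- function(pv) {
        Pv <- compPmf(pv)
        sum((resp * counts) * log(pmax(Pv, 1e-300)))
      }
      pCur <- stats::optimize(obj, c(1e-6, 1), maximum = TRUE, tol = 1e-9)$maximum
    }
    ll <- mixLL(w, pCur)
    if (is.finite(ll) && abs(ll - llOld) < tol) break
    llOld <- ll
  }
  ll <- mixLL(w, pCur)
  boundary <- any(w < 1e-6 | w > 1 - 1e-6)
  if (sum(counts > 0) == 1L) boundary <- TRUE
  new("MixtureFitResult",
      components = data.frame(n = components, weight = w),
      pHat = pCur, pFixed = pFixed, logLik = ll, boundary = boundary)
}

#' Pearson chi-square goodness of fit of a step-count table
#'
#' Compares observed counts to the expectation of a detection-conditional
#' binomial model. Cells with expected count below 1 are pooled downward
#' into the nearest admissible cell (pooling recorded and warned); at
#' least two usable cells are required. Degrees of freedom are
#' \code{cells - 1 - fittedParams}.
#'
#' @param table a \linkS4class{StepCountTable}.
#' @param n,p model subunit count and fluorescence probability.
#' @param fittedParams number of parameters estimated from the data (1
#'   when p was fitted, 0 when fixed).
#' @return list with \code{statistic}, \code{df}, \code{pValue},
#'   \code{pooled} (logical), \code{cells} (number of cells used).
#' @examples
#' tab <- stepCountTable(c(`1` = 248, `2` = 252))
#' goodnessOfFit(tab, n = 2, p = 0.67)
#' @export
goodnessOfFit <- function(table, n, p, fittedParams = 0L) {
  counts <- as.numeric(table@counts)
  N <- sum(counts)
  stopIfNot(N > 0, "empty step-count table")
  kMax <- table@kMax
  if (kMax < 2L) stop("fewer than 2 usable cells", call. = FALSE)
  expected <- numeric(kMax)
  kk <- seq_len(min(n, kMax))
  expected[kk] <- N * conditionalBinomialPmf(n, p, kk)
  # pool cells with expected < 1 downward into the previous cell
  obs <- counts; exp_ <- expected
  pooled <- FALSE
  i <- length(exp_)
  while (i >= 2L) {
    if (exp_[i] < 1) {
      exp_[i - 1L] <- exp_[i - 1L] + exp_[i]
      obs[i - 1L] <- obs[i - 1L] + obs[i]
      exp_ <- exp_[-i]; obs <- obs[-i]
      pooled <- TRUE
    }
    i <- i - 1L
  }
  if (pooled) warning("cells with expected count < 1 were pooled")
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(exp_) - 1L - fittedParams
  list(statistic = stat, df = df,
       pValue = if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE)
                else NA_real_,
       pooled = pooled, cells = length(exp_))
}
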