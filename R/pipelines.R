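#' @include AllClasses.R io.R sim-population.R step-detection.R stoichiometry.R fret.R colocalization.R sim-fret.R sim-coloc.R
NULL

# reject unknown keys before any work happens
checkConfigKeys <- function(config, allowed, where) {
  extra <- setdiff(names(config), allowed)
  if (length(extra))
    stop("unknown ", where, " configuration key(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  invisible(config)
}

bundleProvenance <- function(config, seed, inputFiles = character(0)) {
  list(package = "fluorQuant",
       version = as.character(utils::packageVersion("fluorQuant")),
       seed = seed,
       config = config,
       inputDigests = if (length(inputFiles)) as.list(fileDigests(inputFiles))
                      else stats::setNames(list(), character(0)))
}

makeBundle <- function(results, files, provenance, outDir) {
  writeJsonStable(provenance, file.path(outDir, "provenance.json"))
  new("ReportBundle", results = results,
      files = c(files, file.path(outDir, "provenance.json")),
      provenance = provenance)
}

#' Run the subunit-counting pipeline
#'
#' Chains trace acquisition (simulation, a movie TIFF, or a trace CSV),
#' step detection with quality control, step-count tabulation, conditional
#' binomial fitting, and model selection over candidate subunit counts,
#' writing a reproducible bundle of CSV/JSON results. Re-running with an
#' identical configuration (including the seed) reproduces the bundle byte
#' for byte.
#'
#' @param config named list. Keys: \code{seed} (integer, default 1);
#'   exactly one input block of \code{simulate} (named list of
#'   \code{\link{simConfig}} arguments), \code{movieTiff} (path written by
#'   \code{\link{writeMovieTIFF}}) or \code{tracesCsv} (path written by
#'   \code{\link{writeTraceCSV}}); optional \code{stepParams} (arguments
#'   for \code{\link{stepFitParams}}), \code{detectParams} (arguments for
#'   \code{\link{spotDetectParams}}, movie input only), \code{candidates}
#'   (integer vector, default 1:4), \code{kMax} (default 4). Unknown keys
#'   are rejected.
#' @param outDir output directory (created if needed).
#' @return a \linkS4class{ReportBundle} whose results hold the
#'   \linkS4class{StepCountTable}, all per-candidate fits and the
#'   \linkS4class{ModelSelectionResult}.
#' @examples
#' \donttest{
#' out <- tempfile()
#' b <- runCountingPipeline(list(seed = 1,
#'   simulate = list(nSubunits = 2, nSpots = 200, noiseSd = 0)), out)
#' selectedN(bundleResults(b)$selection)
#' }
#' @export
runCountingPipeline <- function(config, outDir) {
  checkConfigKeys(config, c("seed", "simulate", "movieTiff", "tracesCsv",
                            "stepParams", "detectParams", "candidates",
                            "kMax"), "counting")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  nIn <- sum(!vapply(config[c("simulate", "movieTiff", "tracesCsv")],
                     is.null, logical(1)))
  stopIfNot(nIn == 1,
            "exactly one of 'simulate', 'movieTiff' or 'tracesCsv' required")
  kMax <- if (is.null(config$kMax)) 4L else as.integer(config$kMax)
  sp <- do.call(stepFitParams, c(config$stepParams, list(kMax = kMax)))
  inputFiles <- character(0)

  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    simArgs$seed <- seed
    cfg <- do.call(simConfig, simArgs)
    traces <- simulateSpotPopulation(cfg)$traces
  } else if (!is.null(config$movieTiff)) {
    stopIfNot(file.exists(config$movieTiff),
              paste("missing input file:", config$movieTiff))
    inputFiles <- c(config$movieTiff, paste0(config$movieTiff, ".json"))
    movie <- readMovieTIFF(config$movieTiff)
    dp <- do.call(spotDetectParams, as.list(config$detectParams))
    rois <- detectImmobileSpots(movie, dp)
    stopIfNot(nrow(rois) > 0, "spot detection found no immobile spots")
    traces <- extractTraces(movie, rois)
  } else {
    stopIfNot(file.exists(config$tracesCsv),
              paste("missing input file:", config$tracesCsv))
    inputFiles <- config$tracesCsv
    traces <- readTraceCSV(config$tracesCsv)
  }

  fits <- countSteps(traces, sp)
  tab <- countDistribution(fits, kMax = kMax)
  candidates <- if (is.null(config$candidates)) 1:4
                else as.integer(config$candidates)
  sel <- selectStoichiometry(tab, candidates)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(outDir, "step_fits.csv")
  utils::write.csv(fits, f1, row.names = FALSE)
  f2 <- file.path(outDir, "step_counts.csv")
  writeStepCountCSV(tab, f2)
  selFit <- sel@fits[[paste0("n", sel@selectedN)]]
  f3 <- file.path(outDir, "stoichiometry.json")
  writeJsonStable(list(
    candidates = sel@table,
    selectedN = sel@selectedN,
    selectionMargin = sel@selectionMargin,
    selected = list(n = selFit@n, pHat = selFit@pHat, pCI = selFit@pCI,
                    logLik = selFit@logLik, chiSquare = selFit@chiSquare,
                    df = selFit@df)), f3)
  f4 <- file.path(outDir, "observed_vs_expected.csv")
  utils::write.csv(data.frame(k = seq_len(kMax),
                              observedFreq = tab@counts / tab@totalSpots,
                              expectedFreq = selFit@expectedFreqs),
                   f4, row.names = FALSE)
  prov <- bundleProvenance(config, seed, inputFiles)
  makeBundle(list(stepFits = fits, counts = tab, selection = sel),
             c(f1, f2, f3, f4), prov, outDir)
}

#' Run the acceptor-photobleaching FRET pipeline
#'
#' Computes per-cell FRET efficiencies (with scan-loss correction and the
#' acceptor-bleach QC gate) for a batch of simulated or file-based image
#' sets, plus the group summary.
#'
#' @param config named list. Keys: \code{seed}; either \code{simulate}
#'   (named list: \code{nCells}, plus arguments of
#'   \code{\link{simulateFretPair}}) or \code{inputs} (list of per-cell
#'   named lists with TIFF paths \code{donorPre}, \code{donorPost},
#'   \code{acceptorPre}, \code{acceptorPost} and mask TIFFs
#'   \code{bleachRoi}, \code{controlRoi}); optional \code{qcMinBleach}
#'   (default 0.7) and \code{label}. Unknown keys are rejected.
#' @param outDir output directory.
#' @return a \linkS4class{ReportBundle} with per-cell results and the
#'   group summary.
#' @export
runFretPipeline <- function(config, outDir) {
  checkConfigKeys(config, c("seed", "simulate", "inputs", "qcMinBleach",
                            "label"), "fret")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  qc <- if (is.null(config$qcMinBleach)) 0.7 else config$qcMinBleach
  label <- if (is.null(config$label)) "group" else config$label
  stopIfNot(xor(is.null(config$simulate), is.null(config$inputs)),
            "exactly one of 'simulate' or 'inputs' required")
  inputFiles <- character(0)
  if (!is.null(config$simulate)) {
    sa <- config$simulate
    nCells <- if (is.null(sa$nCells)) 1L else as.integer(sa$nCells)
    sa$nCells <- NULL
    sets <- lapply(seq_len(nCells), function(i) {
      do.call(simulateFretPair,
              c(sa, list(seed = derivedSeed(seed, paste0("fret-cell-", i)),
                         cellId = sprintf("cell%03d", i))))
    })
  } else {
    sets <- lapply(seq_along(config$inputs), function(i) {
      inp <- config$inputs[[i]]
      for (f in unlist(inp))
        stopIfNot(file.exists(f), paste("missing input file:", f))
      inputFiles <<- c(inputFiles, unlist(inp))
      new("FretImageSet",
          donorPre = readImageTIFF(inp$donorPre),
          donorPost = readImageTIFF(inp$donorPost),
          acceptorPre = readImageTIFF(inp$acceptorPre),
          acceptorPost = readImageTIFF(inp$acceptorPost),
          bleachRoi = readImageTIFF(inp$bleachRoi) > 0.5,
          controlRoi = readImageTIFF(inp$controlRoi) > 0.5,
          cellId = if (is.null(inp$cellId)) sprintf("cell%03d", i)
                   else inp$cellId)
    })
  }
  results <- lapply(sets, computeFretEfficiency, qcMinBleach = qc)
  percell <- do.call(rbind, lapply(results, function(r)
    data.frame(cellId = r@cellId, fBefore = r@fBefore,
               fAfterRaw = r@fAfterRaw, scanFactor = r@scanFactor,
               fAfterCorrected = r@fAfterCorrected,
               efficiencyPct = r@efficiencyPct,
               efficiencyCanonicalPct = r@efficiencyCanonicalPct,
               bleachDepth = r@bleachDepth, passedQc = r@passedQc,
               stringsAsFactors = FALSE)))
  summary <- summarizeGroup(results, label = label)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(outDir, "fret_cells.csv")
  utils::write.csv(percell, f1, row.names = FALSE)
  f2 <- file.path(outDir, "fret_summary.csv")
  utils::write.csv(summary, f2, row.names = FALSE)
  prov <- bundleProvenance(config, seed, inputFiles)
  makeBundle(list(cells = results, percell = percell, summary = summary),
             c(f1, f2), prov, outDir)
}

#' Run the colocalization / decay pipeline
#'
#' Per-cell Mander's coefficients and regulator/reporter ratios, followed
#' by the exponential-decay fit of ER colocalization against the
#' expression ratio.
#'
#' @param config named list. Keys: \code{seed}; either \code{simulate}
#'   (named list: \code{ratios} plus arguments of
#'   \code{\link{simulateColocPanel}}) or \code{inputs} (list of per-cell
#'   named lists with TIFF paths \code{reporter}, \code{er},
#'   \code{regulator}, \code{cellMask}); optional \code{method}
#'   (threshold method, default "otsu") and \code{fixC}. Unknown keys are
#'   rejected.
#' @param outDir output directory.
#' @return a \linkS4class{ReportBundle} with the per-cell table and the
#'   \linkS4class{DecayFit}.
#' @export
runColocPipeline <- function(config, outDir) {
  checkConfigKeys(config, c("seed", "simulate", "inputs", "method", "fixC"),
                  "coloc")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  method <- if (is.null(config$method)) "otsu" else config$method
  fixC <- isTRUE(config$fixC)
  stopIfNot(xor(is.null(config$simulate), is.null(config$inputs)),
            "exactly one of 'simulate' or 'inputs' required")
  inputFiles <- character(0)
  if (!is.null(config$simulate)) {
    sa <- config$simulate
    sa$seed <- seed
    sets <- do.call(simulateColocPanel, sa)$sets
  } else {
    sets <- lapply(seq_along(config$inputs), function(i) {
      inp <- config$inputs[[i]]
      for (f in unlist(inp[c("reporter", "er", "regulator", "cellMask")]))
        stopIfNot(file.exists(f), paste("missing input file:", f))
      inputFiles <<- c(inputFiles,
                       unlist(inp[c("reporter", "er", "regulator", "cellMask")]))
      new("ColocImageSet",
          channels = list(reporter = readImageTIFF(inp$reporter),
                          er = readImageTIFF(inp$er),
                          regulator = readImageTIFF(inp$regulator)),
          cellMask = readImageTIFF(inp$cellMask) > 0.5,
          acquisition = if (is.null(inp$acquisition)) list()
                        else inp$acquisition,
          cellId = if (is.null(inp$cellId)) sprintf("cell%03d", i)
                   else inp$cellId)
    })
  }
  pts <- perCellRatioAnalysis(sets, method = method)
  fit <- fitExponentialDecay(data.frame(x = pts$ratio, y = pts$erColoc),
                             fixC = fixC)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(outDir, "coloc_cells.csv")
  utils::write.csv(pts, f1, row.names = FALSE)
  f2 <- file.path(outDir, "decay_fit.json")
  writeJsonStable(list(amplitude = fit@amplitude, rate = fit@rate,
                       offset = fit@offset, rSquared = fit@rSquared,
                       sse = fit@sse, nCells = fit@nCells, flat = fit@flat),
                  f2)
  prov <- bundleProvenance(config, seed, inputFiles)
  makeBundle(list(points = pts, decay = fit), c(f1, f2), prov, outDir)
}
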