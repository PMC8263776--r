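#' @include AllClasses.R utils.R
NULL

# stable JSON writer used for every bundle file: unboxed scalars, full
# precision, fixed key order as supplied
writeJsonStable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a movie stack as a multi-frame grayscale TIFF
#'
#' Frames are stored as 32-bit float samples scaled to [0, 1]; the scale
#' factor and frame interval travel in a JSON sidecar next to the TIFF
#' (same path plus ".json"). Writing is reproducible byte for byte for a
#' given movie.
#'
#' @param movie a \linkS4class{MovieStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeMovieTIFF <- function(movie, path) {
  validObject(movie)
  d <- movie@data
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(d)[1]), function(f) (d[f, , ] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  writeJsonStable(list(offset = lo, scale = scale,
                       frameInterval = movie@frameInterval),
                  paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(path) {
  stopIfNot(file.exists(path), paste("missing input file:", path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(frames), dim(frames[[1]])[1], dim(frames[[1]])[2]))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]] * meta$scale + meta$offset
  new("MovieStack", data = arr, frameInterval = meta$frameInterval)
}

#' Write / read a single grayscale image as TIFF
#'
#' Same 32-bit float convention and JSON sidecar as
#' \code{\link{writeMovieTIFF}}.
#'
#' @param img numeric matrix.
#' @param path output TIFF path.
#' @return \code{path} (write) or the matrix (read).
#' @export
writeImageTIFF <- function(img, path) {
  lo <- min(img); hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 32L)
  writeJsonStable(list(offset = lo, scale = scale), paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  stopIfNot(file.exists(path), paste("missing input file:", path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tiff::readTIFF(path) * meta$scale + meta$offset
}

#' Write / read bleaching traces as long-format CSV
#'
#' Columns: spotId, frame (1-based), time_s, intensity (background
#' corrected, a.u.), background (a.u. subtracted per frame).
#'
#' @param traces a \linkS4class{BleachTraces}.
#' @param path CSV path.
#' @return \code{path} (write) or a \linkS4class{BleachTraces} (read).
#' @export
writeTraceCSV <- function(traces, path) {
  validObject(traces)
  v <- traces@values
  nF <- ncol(v)
  df <- data.frame(
    spotId = rep(traces@spotId, each = nF),
    frame = rep(seq_len(nF), times = nrow(v)),
    time_s = rep((seq_len(nF) - 1) * traces@frameInterval, times = nrow(v)),
    intensity = as.vector(t(v)),
    background = rep(traces@background, each = nF))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCSV
#' @export
readTraceCSV <- function(path) {
  stopIfNot(file.exists(path), paste("missing input file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spotId", "frame", "time_s", "intensity", "background")
  stopIfNot(all(need %in% names(df)), "trace CSV is missing required columns")
  ids <- unique(df$spotId)
  nF <- max(df$frame)
  v <- matrix(NA_real_, length(ids), nF)
  bg <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$spotId == ids[i], ]
    v[i, sub$frame] <- sub$intensity
    bg[i] <- sub$background[1]
  }
  stopIfNot(all(is.finite(v)), "trace CSV has missing frames")
  dt <- if (nF > 1) df$time_s[df$frame == 2][1] - df$time_s[df$frame == 1][1]
        else 1
  new("BleachTraces", values = v, spotId = as.character(ids),
      frameInterval = dt, background = bg)
}

#' Write / read a step-count table as CSV
#'
#' Columns: k, count.
#'
#' @param table a \linkS4class{StepCountTable}.
#' @param path CSV path.
#' @return \code{path} (write) or a \linkS4class{StepCountTable} (read).
#' @export
writeStepCountCSV <- function(table, path) {
  utils::write.csv(data.frame(k = seq_len(table@kMax), count = table@counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStepCountCSV
#' @export
readStepCountCSV <- function(path) {
  stopIfNot(file.exists(path), paste("missing input file:", path))
  df <- utils::read.csv(path)
  stopIfNot(all(c("k", "count") %in% names(df)),
            "step-count CSV needs columns k and count")
  stepCountTable(stats::setNames(df$count, df$k))
}
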