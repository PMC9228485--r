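#' Region mean intensities of an MRI slice series
#'
#' Arithmetic mean pixel intensity under the stem, water-reference and air
#' masks of each slice at each timepoint.
#'
#' @param series an [MriSeries-class].
#' @return list of \code{[slice, time]} matrices \code{stem, water, air}.
#' @export
regionMeans <- function(series) {
  stopifnot(is(series, "MriSeries"))
  d <- dim(series@data)
  out <- list(stem = NULL, water = NULL, air = NULL)
  codes <- c(stem = 1L, water = 2L, air = 3L)
  for (nm in names(codes)) {
    m <- matrix(NA_real_, d[1], d[2])
    for (i in seq_len(d[1])) {
      sel <- series@masks[i, , ] == codes[[nm]]
      if (!any(sel)) {
        if (nm != "water") stop(sprintf("empty %s mask in slice %d", nm, i))
        next
      }
      for (t in seq_len(d[2])) m[i, t] <- mean(series@data[i, t, , ][sel])
    }
    out[[nm]] <- m
  }
  out
}

#' Normalized flow-signal matrix
#'
#' For each slice i and timepoint t the flow signal is the baseline-
#' subtracted stem mean divided by the concurrent air mean:
#' \deqn{F_{it} = \frac{S(stem_{it}) - S(stem_{i0})}{S(air_{it})},}
#' computed for each slice at each time point. The air mean at the same
#' timepoint divides (no temporal smoothing), and the baseline is the first
#' timepoint. Slices whose air mean is not strictly positive at every
#' timepoint are a division hazard and raise an error naming the slice.
#'
#' @param stemMean,airMean \code{[slice, time]} matrices (e.g. from
#'   [regionMeans()]).
#' @param timeStep minutes between timepoints (default 23).
#' @param sliceSpacing mm between slices (default 1).
#' @return a [FlowSignalMatrix-class]; the first column is exactly zero.
#' @examples
#' stem <- matrix(c(100, 110), 1)   # one slice, two timepoints
#' air <- matrix(c(25, 25), 1)
#' flowMatrix(normalizeFlowSignal(stem, air))  # 0, 0.4
#' @export
normalizeFlowSignal <- function(stemMean, airMean, timeStep = 23,
                                sliceSpacing = 1) {
  if (!identical(dim(stemMean), dim(airMean)))
    stop("stem and air mean matrices must have identical shape")
  bad <- which(apply(airMean <= 0, 1, any))
  if (length(bad))
    stop(sprintf("non-positive air mean in slice(s) %s",
                 paste(bad, collapse = ", ")))
  f <- (stemMean - stemMean[, 1]) / airMean
  f[, 1] <- 0  # exact baseline
  new("FlowSignalMatrix", values = f,
      slicePositions = (seq_len(nrow(f)) - 1) * sliceSpacing,
      timeMinutes = (seq_len(ncol(f)) - 1) * timeStep)
}

#' Flow-signal matrix of a series in one call
#'
#' @param series an [MriSeries-class].
#' @return a [FlowSignalMatrix-class].
#' @export
flowSignal <- function(series) {
  rm <- regionMeans(series)
  normalizeFlowSignal(rm$stem, rm$air, timeStep = series@timeStep,
                      sliceSpacing = series@sliceSpacing)
}

#' Classify slices as signal-accumulating (node) or not (internode)
#'
#' Fits a least-squares slope to each slice's flow signal against time;
#' slices with slope above the threshold are labeled nodal plexus
#' (contrast-filtering), the rest internode. For real data the threshold
#' must be chosen explicitly; for phantoms [defaultSlopeThreshold()]
#' derives it from the generator truth.
#'
#' @param F a [FlowSignalMatrix-class] with >= 3 timepoints.
#' @param slopeThreshold slope threshold in flow-signal units per minute.
#' @return data.frame with \code{slice, slope, class}.
#' @export
classifySlices <- function(F, slopeThreshold) {
  stopifnot(is(F, "FlowSignalMatrix"))
  if (ncol(F@values) < 3) stop("need at least 3 timepoints")
  t <- F@timeMinutes
  tc <- t - mean(t)
  slope <- as.vector(F@values %*% tc) / sum(tc^2)
  data.frame(slice = seq_len(nrow(F@values)), slope = slope,
             class = ifelse(slope > slopeThreshold, "node", "internode"))
}

#' Default classification threshold from phantom truth
#'
#' Half the median flow-signal slope of the phantom's node-class slices:
#' a calibration usable whenever ground truth (or an annotated training
#' series) is available.
#'
#' @param series an [MriSeries-class] with truth classes.
#' @return slope threshold (flow-signal units per minute).
#' @export
defaultSlopeThreshold <- function(series) {
  stopifnot(is(series, "MriSeries"))
  if (!length(series@truth)) stop("series carries no truth classes")
  F <- flowSignal(series)
  t <- F@timeMinutes
  tc <- t - mean(t)
  slope <- as.vector(F@values %*% tc) / sum(tc^2)
  node <- series@truth$class == "node"
  0.5 * stats::median(slope[node])
}

#' Space-time map of the flow signal
#'
#' Writes the flow-signal matrix as CSV (slices in rows, timepoints in
#' columns, units in the header) and renders the slice-position x time map
#' to PNG.
#'
#' @param F a [FlowSignalMatrix-class].
#' @param csvPath,pngPath output paths (either may be NULL to skip).
#' @return invisibly, the matrix written.
#' @export
spacetimeMap <- function(F, csvPath = NULL, pngPath = NULL) {
  stopifnot(is(F, "FlowSignalMatrix"))
  m <- F@values
  if (!is.null(csvPath)) {
    df <- data.frame(slice_position_mm = F@slicePositions, m)
    names(df)[-1] <- sprintf("t_%g_min", F@timeMinutes)
    utils::write.csv(df, csvPath, row.names = FALSE)
  }
  if (!is.null(pngPath)) {
    grDevices::png(pngPath, width = 640, height = 480)
    on.exit(grDevices::dev.off())
    graphics::image(x = F@timeMinutes, y = F@slicePositions, z = t(m),
                    xlab = "time (min)", ylab = "slice position (mm)",
                    main = "Normalized flow signal", useRaster = TRUE)
  }
  invisible(m)
}

#' Read back a space-time CSV into a matrix
#'
#' @param csvPath file written by [spacetimeMap()].
#' @return a [FlowSignalMatrix-class].
#' @export
readSpacetimeCsv <- function(csvPath) {
  df <- utils::read.csv(csvPath, check.names = FALSE)
  if (names(df)[1] != "slice_position_mm")
    stop("malformed space-time CSV: first column must be slice_position_mm")
  tm <- as.numeric(sub("^t_(.*)_min$", "\\1", names(df)[-1]))
  if (any(is.na(tm)))
    stop(sprintf("malformed space-time CSV: bad time column '%s'",
                 names(df)[-1][which(is.na(tm))[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  new("FlowSignalMatrix", values = m, slicePositions = df[[1]],
      timeMinutes = tm)
}
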