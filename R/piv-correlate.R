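#' PIV interrogation configuration
#'
#' @param initialWindow,finalWindow \code{c(h, w)} window sizes in px; the
#'   long axis lies along the flow (x). Defaults 32x128 -> 8x32 (h x w),
#'   i.e. 128x32 -> 32x8 in the field's w x h notation.
#' @param nPasses number of passes (default 3: 128x32, 64x16, 32x8).
#' @param overlap window overlap fraction (default 0.5).
#' @param snrThreshold peak-ratio validation threshold (default 2).
#' @param medianRegion \code{c(h, w)} normalized-median region (default 7x7).
#' @param dt interframe time in seconds (default 1).
#' @param calibration micrometres per pixel (default 1).
#' @return a [PivConfig-class].
#' @export
pivConfig <- function(initialWindow = c(32, 128), finalWindow = c(8, 32),
                      nPasses = 3, overlap = 0.5, snrThreshold = 2,
                      medianRegion = c(7, 7), dt = 1, calibration = 1) {
  new("PivConfig", initialWindow = as.integer(initialWindow),
      finalWindow = as.integer(finalWindow), nPasses = as.integer(nPasses),
      overlap = overlap, snrThreshold = snrThreshold,
      medianRegion = as.integer(medianRegion), dt = dt,
      calibration = calibration)
}

#' Cross-correlate an interrogation window pair
#'
#' Zero-normalized cross-correlation (windows mean-subtracted and scaled to
#' unit norm internally) over integer lags within the half-window search
#' range. The secondary peak used for the signal-to-noise ratio is searched
#' outside a 3x3 exclusion zone around the primary peak.
#'
#' @param winA,winB numeric matrices of identical shape \code{[y, x]}.
#' @param maxLag optional integer \code{c(y, x)} half-extent of the search
#'   range; default half the window in each dimension.
#' @return a [CorrelationPlane-class]; \code{valid = FALSE} with an all-NA
#'   plane when either window has zero variance (flat texture).
#' @examples
#' set.seed(1)
#' w <- matrix(runif(32 * 8), 8, 32)
#' correlateWindow(w, w)  # peak at zero lag
#' @export
correlateWindow <- function(winA, winB, maxLag = NULL) {
  if (!identical(dim(winA), dim(winB)))
    stop("windows must have identical dimensions")
  if (is.null(maxLag)) maxLag <- dim(winA) %/% 2
  maxLag <- as.integer(maxLag)
  vals <- cpp_xcorr_plane(winA, winB, maxLag[1], maxLag[2])
  if (any(is.na(vals)))
    return(new("CorrelationPlane", values = vals, maxLag = maxLag,
               peakLag = c(NA_integer_, NA_integer_), peakValue = NA_real_,
               secondaryValue = NA_real_, valid = FALSE))
  pk <- arrayInd(which.max(vals), dim(vals))
  peakLag <- as.integer(c(pk[1] - maxLag[1] - 1, pk[2] - maxLag[2] - 1))
  masked <- vals
  r0 <- max(1, pk[1] - 1):min(nrow(vals), pk[1] + 1)
  c0 <- max(1, pk[2] - 1):min(ncol(vals), pk[2] + 1)
  masked[r0, c0] <- -Inf
  secondary <- max(masked)
  new("CorrelationPlane", values = vals, maxLag = maxLag, peakLag = peakLag,
      peakValue = vals[pk[1], pk[2]],
      secondaryValue = if (is.finite(secondary)) secondary else 0,
      valid = TRUE)
}

#' Three-point Gaussian subpixel peak interpolation
#'
#' Refines the integer correlation peak with the one-dimensional
#' log-Gaussian three-point estimator, applied independently along each
#' axis: \deqn{\delta = \frac{\ln R_{-1} - \ln R_{+1}}
#' {2\ln R_{-1} + 2\ln R_{+1} - 4\ln R_0}.}
#' The estimator is exact when the sampled peak is a pure Gaussian. Values
#' are floor-shifted to a small positive minimum before taking logs; if any
#' point of a triple is non-positive even after the shift is inapplicable
#' (degenerate plane), the axis falls back to a three-point parabolic fit
#' and the result is flagged.
#'
#' @param plane a valid [CorrelationPlane-class] whose primary peak is
#'   strictly interior to the lag range.
#' @return list with \code{lag} (numeric \code{c(dy, dx)} including the
#'   subpixel offset, each |offset| < 1) and \code{gaussian} (logical per
#'   axis; FALSE where the parabolic fallback was used).
#' @export
subpixelPeak <- function(plane) {
  stopifnot(is(plane, "CorrelationPlane"))
  if (!plane@valid) stop("cannot interpolate an invalid correlation plane")
  vals <- plane@values
  pk <- plane@peakLag + plane@maxLag + 1L
  if (pk[1] <= 1 || pk[1] >= nrow(vals) || pk[2] <= 1 || pk[2] >= ncol(vals))
    stop("primary peak lies on the plane border")
  axis1 <- vals[(pk[1] - 1):(pk[1] + 1), pk[2]]
  axis2 <- vals[pk[1], (pk[2] - 1):(pk[2] + 1)]
  res <- vapply(list(axis1, axis2), function(r) {
    if (r[2] < r[1] || r[2] < r[3])
      stop("center of the three-point triple is not a local maximum")
    gauss <- TRUE
    rs <- pmax(r, 1e-6)
    denom <- 2 * log(rs[1]) + 2 * log(rs[3]) - 4 * log(rs[2])
    if (any(r <= 0) || abs(denom) < 1e-300) {
      # parabolic fallback
      gauss <- FALSE
      den <- r[1] - 2 * r[2] + r[3]
      delta <- if (abs(den) < 1e-300) 0 else 0.5 * (r[1] - r[3]) / den
    } else {
      delta <- (log(rs[1]) - log(rs[3])) / denom
    }
    if (!is.finite(delta) || abs(delta) >= 1) delta <- 0
    c(delta, gauss)
  }, numeric(2))
  list(lag = c(plane@peakLag[1] + res[1, 1], plane@peakLag[2] + res[1, 2]),
       gaussian = as.logical(res[2, ]))
}
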