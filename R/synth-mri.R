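#' Generate a contrast-enhanced MRI phantom series
#'
#' Emulates the slice time-series of a stem acquisition after a gadolinium
#' contrast agent is presented to the roots: slices through nodal plexuses
#' accumulate stem-region signal following a saturating exponential
#' \eqn{S_0 + A (1 - e^{-t/\tau})}, internode slices stay at baseline, and
#' the water-reference and air regions are time-constant. Gaussian noise is
#' added everywhere. Masks (stem disk, water-reference disk, air frame) are
#' fixed per slice across time.
#'
#' @param nSlices,nTimes series dimensions (defaults 18 slices, 19
#'   timepoints, the acquisition layout of an 18 mm stem window scanned
#'   every 23 min for 7 h).
#' @param height,width in-plane frame size in px.
#' @param nodeSlices integer indices of accumulating (nodal-plexus) slices;
#'   default \code{c(1:3, 8:10, 16:18)}, three node regions separated by
#'   internodes.
#' @param stemBase,waterMean,airMean baseline region intensities (arbitrary
#'   scanner units).
#' @param amplitude saturation amplitude A of node slices (internode slices
#'   have A = 0).
#' @param tau accumulation time constant in minutes.
#' @param noiseSd per-pixel Gaussian noise sd.
#' @param timeStep minutes between acquisitions (default 23).
#' @param sliceSpacing mm between slices (default 1).
#' @param seed integer seed (bit-reproducible).
#' @return an [MriSeries-class] whose \code{truth} lists per-slice class
#'   ("node"/"internode"), amplitude, tau and baselines.
#' @examples
#' ser <- makeMriPhantom(nSlices = 4, nTimes = 6, nodeSlices = c(1, 3),
#'                       height = 16, width = 16, seed = 2)
#' ser
#' @export
makeMriPhantom <- function(nSlices = 18, nTimes = 19, height = 32, width = 32,
                           nodeSlices = c(1:3, 8:10, 16:18),
                           stemBase = 100, waterMean = 150, airMean = 25,
                           amplitude = 50, tau = 100, noiseSd = 2,
                           timeStep = 23, sliceSpacing = 1, seed = 1) {
  if (nSlices < 2) stop("need at least 2 slices")
  nodeSlices <- nodeSlices[nodeSlices <= nSlices]
  if (length(nodeSlices) < 1 || length(nodeSlices) >= nSlices)
    stop("need at least one node and one internode slice")
  if (noiseSd < 0) stop("noiseSd must be non-negative")

  masks <- array(0L, dim = c(nSlices, height, width))
  yy <- outer(seq_len(height) - 0.5, rep(1, width))
  xx <- outer(rep(1, height), seq_len(width) - 0.5)
  stemR <- min(height, width) / 4
  stem <- (yy - height / 2)^2 + (xx - width / 2)^2 <= stemR^2
  water <- (yy - height / 5)^2 + (xx - width / 5)^2 <= (min(height, width) / 8)^2
  water <- water & !stem
  air <- !(stem | water) &
    (yy > 0.75 * height | xx > 0.75 * width)  # outer corner, away from stem
  m <- matrix(0L, height, width)
  m[stem] <- 1L; m[water] <- 2L; m[air] <- 3L
  for (i in seq_len(nSlices)) masks[i, , ] <- m

  cls <- ifelse(seq_len(nSlices) %in% nodeSlices, "node", "internode")
  amp <- ifelse(cls == "node", amplitude, 0)
  tmin <- (seq_len(nTimes) - 1) * timeStep

  dat <- withSeed(seed, {
    a <- array(0, dim = c(nSlices, nTimes, height, width))
    for (i in seq_len(nSlices)) {
      for (t in seq_len(nTimes)) {
        frame <- matrix(airMean, height, width)
        frame[water] <- waterMean
        frame[stem] <- stemBase + amp[i] * (1 - exp(-tmin[t] / tau))
        if (noiseSd > 0)
          frame <- frame + matrix(stats::rnorm(height * width, 0, noiseSd),
                                  height, width)
        a[i, t, , ] <- frame
      }
    }
    a
  })
  new("MriSeries", data = dat, masks = masks, sliceSpacing = sliceSpacing,
      timeStep = timeStep,
      truth = list(class = cls, amplitude = amp, tau = tau,
                   stemBase = stemBase, waterMean = waterMean,
                   airMean = airMean, noiseSd = noiseSd,
                   seed = as.integer(seed)))
}

#' Construct an MriSeries from raw components
#'
#' For measured data: wrap an intensity array and mask array read from TIFF
#' stacks into the container the analysis operations consume.
#'
#' @param data numeric array \code{[slice, time, y, x]}.
#' @param masks integer array \code{[slice, y, x]} coded 0/1/2/3 =
#'   none/stem/water/air.
#' @param timeStep minutes between timepoints.
#' @param sliceSpacing mm between slices.
#' @return an [MriSeries-class].
#' @export
mriSeries <- function(data, masks, timeStep = 23, sliceSpacing = 1) {
  new("MriSeries", data = data, masks = masks, sliceSpacing = sliceSpacing,
      timeStep = timeStep, truth = list())
}
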