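#' @useDynLib xylemflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' DisplacementField: a prescribed planar motion with known ground truth
#'
#' A displacement field maps pixel positions \code{(x, y)} to displacements
#' \code{(dx, dy)} in pixels per frame interval. Fields are the ground truth
#' consumed by [makeParticleImagePair()] and recovered by the PIV engine.
#'
#' @slot fun a vectorized function of numeric vectors \code{x, y} (pixel
#'   coordinates) returning a two-column matrix \code{cbind(dx, dy)}.
#' @slot width,height domain size in pixels (x spans \code{[0, width]},
#'   y spans \code{[0, height]}).
#' @slot kind descriptive tag: \code{"uniform"}, \code{"poiseuille"} or
#'   \code{"y-merge"}.
#' @slot params named list of the parameters the field was built from.
#'
#' @seealso [uniformField()], [poiseuilleField()], [yMergeField()]
#' @export
setClass("DisplacementField",
  representation(fun = "function", width = "numeric", height = "numeric",
                 kind = "character", params = "list"),
  validity = function(object) {
    if (length(object@width) != 1 || length(object@height) != 1 ||
        object@width <= 0 || object@height <= 0)
      return("width and height must be positive scalars")
    if (!object@kind %in% c("uniform", "poiseuille", "y-merge", "custom"))
      return("kind must be uniform, poiseuille, y-merge or custom")
    probe <- object@fun(c(0, object@width / 2), c(0, object@height / 2))
    if (!is.matrix(probe) || ncol(probe) != 2 || !all(is.finite(probe)))
      return("fun must return a finite two-column matrix (dx, dy)")
    TRUE
  })

#' ParticleImagePair: a synthetic tracer-image pair with known displacement
#'
#' Two 8-bit grayscale frames of Gaussian tracer particles in which every
#' frame-B particle is the corresponding frame-A particle displaced by the
#' truth field, plus the generating parameters. Regenerating with the same
#' seed and parameters is bit-exact.
#'
#' @slot frameA,frameB integer-valued intensity matrices in \code{[0, 255]},
#'   indexed \code{[y, x]}.
#' @slot truth the generating [DisplacementField-class].
#' @slot params named list: \code{density} (particles/px^2), \code{diameter}
#'   (e^-2 Gaussian diameter, px), \code{intensity} (peak value),
#'   \code{noiseSd} (additive Gaussian noise sd, counts).
#' @slot seed integer seed the pair was generated from.
#' @export
setClass("ParticleImagePair",
  representation(frameA = "matrix", frameB = "matrix",
                 truth = "DisplacementField", params = "list",
                 seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@frameA), dim(object@frameB)))
      return("frames must share dimensions")
    rng <- range(object@frameA, object@frameB)
    if (rng[1] < 0 || rng[2] > 255)
      return("frame intensities must lie in [0, 255]")
    TRUE
  })

#' PivConfig: interrogation parameters for the multipass PIV engine
#'
#' Window sizes follow the convention \code{c(h, w)} with the long axis along
#' the flow (x). The defaults mirror standard micro-PIV practice for slow
#' channel flows: elongated 128x32 initial windows refined to 32x8, 50\%
#' overlap, SNR threshold 2 and a 7x7 normalized-median validation region.
#'
#' @slot initialWindow,finalWindow integer \code{c(h, w)} window sizes in px.
#' @slot nPasses number of refinement passes (window sizes interpolated
#'   geometrically between initial and final).
#' @slot overlap overlap fraction in \code{[0, 0.75]}.
#' @slot snrThreshold minimum primary/secondary correlation peak ratio.
#' @slot medianRegion odd \code{c(h, w)} neighborhood of the normalized
#'   median test, in grid nodes.
#' @slot dt interframe time in seconds.
#' @slot calibration pixel calibration in micrometres per pixel.
#' @seealso [pivConfig()], [multipassPiv()]
#' @export
setClass("PivConfig",
  representation(initialWindow = "integer", finalWindow = "integer",
                 nPasses = "integer", overlap = "numeric",
                 snrThreshold = "numeric", medianRegion = "integer",
                 dt = "numeric", calibration = "numeric"),
  validity = function(object) {
    iw <- object@initialWindow; fw <- object@finalWindow
    if (length(iw) != 2 || length(fw) != 2 || any(iw < 4) || any(fw < 4))
      return("windows must be c(h, w) with entries >= 4")
    if (any(fw > iw))
      return("windows must shrink (finalWindow <= initialWindow)")
    if (object@overlap < 0 || object@overlap > 0.75)
      return("overlap must lie in [0, 0.75]")
    if (object@snrThreshold <= 1)
      return("snrThreshold must exceed 1")
    if (any(object@medianRegion %% 2 != 1))
      return("medianRegion must be odd in both dimensions")
    if (object@dt <= 0 || object@calibration <= 0)
      return("dt and calibration must be positive")
    if (object@nPasses < 1) return("nPasses must be >= 1")
    TRUE
  })

#' CorrelationPlane: normalized cross-correlation over integer lags
#'
#' @slot values correlation matrix over lags; row = dy, col = dx, zero lag at
#'   the center.
#' @slot maxLag integer \code{c(y, x)} half-extent of the lag range.
#' @slot peakLag integer \code{c(dy, dx)} of the primary peak.
#' @slot peakValue,secondaryValue primary and secondary peak heights; the
#'   secondary is searched outside a 3x3 exclusion zone around the primary.
#' @slot valid FALSE for flat-texture (zero-variance) windows.
#' @export
setClass("CorrelationPlane",
  representation(values = "matrix", maxLag = "integer", peakLag = "integer",
                 peakValue = "numeric", secondaryValue = "numeric",
                 valid = "logical"),
  validity = function(object) {
    if (object@valid) {
      d <- dim(object@values)
      if (d[1] != 2 * object@maxLag[1] + 1 || d[2] != 2 * object@maxLag[2] + 1)
        return("plane dimensions must match the lag range")
      if (object@peakValue < object@secondaryValue)
        return("primary peak must be >= secondary peak")
    }
    TRUE
  })

#' VelocityField: a vector field on a regular interrogation grid
#'
#' Velocities are stored in px/frame; calibrated values in um/s are obtained
#' as \code{px/frame * calibration / dt}. Nodes rejected by validation are
#' flagged \code{valid = FALSE}; where a neighborhood-median replacement was
#' substituted, \code{replaced = TRUE} and \code{u, v} hold the replacement.
#'
#' @slot x,y grid node coordinates in px (pixel-center convention).
#' @slot u,v displacement components (px/frame), \code{[length(y), length(x)]}.
#' @slot snr per-node primary/secondary correlation peak ratio.
#' @slot valid,replaced logical matrices, same shape as \code{u}.
#' @slot passIndex pass the field was produced by.
#' @slot calibration um/px; \code{dt} interframe time (s).
#' @slot dt interframe time in seconds.
#' @export
setClass("VelocityField",
  representation(x = "numeric", y = "numeric", u = "matrix", v = "matrix",
                 snr = "matrix", valid = "matrix", replaced = "matrix",
                 passIndex = "integer", calibration = "numeric",
                 dt = "numeric"),
  validity = function(object) {
    d <- c(length(object@y), length(object@x))
    for (nm in c("u", "v", "snr", "valid", "replaced"))
      if (!identical(dim(slot(object, nm)), d))
        return(sprintf("slot %s must be length(y) x length(x)", nm))
    TRUE
  })

#' VesselPhantom: a synthetic labeled vessel cross-section with ground truth
#'
#' @slot labelImage integer matrix; 0 = background, vessels labeled by
#'   consecutive positive integers.
#' @slot truth data.frame with one row per label: \code{label, cx_px, cy_px,
#'   a_px, b_px, theta_rad, ring} (centers/axes in px, pixel-center
#'   convention; ring in I..IV).
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("VesselPhantom",
  representation(labelImage = "matrix", truth = "data.frame",
                 pixelSize = "numeric"),
  validity = function(object) {
    labs <- sort(unique(as.vector(object@labelImage)))
    labs <- labs[labs != 0]
    if (length(labs) != nrow(object@truth) ||
        !identical(as.integer(labs), seq_len(nrow(object@truth))))
      return("labels must be consecutive 1..n matching the truth table")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  })

#' MriSeries: an MRI slice time-series with region masks
#'
#' Holds the intensity array of a contrast-enhanced acquisition (or phantom)
#' indexed \code{[slice, time, y, x]} together with per-slice region masks
#' coding stem, water reference and air. For phantoms, \code{truth} carries
#' the per-slice class and accumulation parameters.
#'
#' @slot data numeric 4-d array \code{[slice, time, y, x]}.
#' @slot masks integer 3-d array \code{[slice, y, x]}; 0 none, 1 stem,
#'   2 water reference, 3 air (masks are disjoint by construction).
#' @slot sliceSpacing slice spacing in mm.
#' @slot timeStep sampling interval in minutes.
#' @slot truth list (possibly empty): \code{class} (character, node or
#'   internode per slice), \code{amplitude}, \code{tau}, baselines, seed.
#' @export
setClass("MriSeries",
  representation(data = "array", masks = "array", sliceSpacing = "numeric",
                 timeStep = "numeric", truth = "list"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4) return("data must be [slice, time, y, x]")
    if (!identical(dim(object@masks), d[c(1, 3, 4)]))
      return("masks must be [slice, y, x] matching data")
    if (!all(object@masks %in% 0:3))
      return("mask codes must be 0 (none), 1 (stem), 2 (water), 3 (air)")
    for (i in seq_len(d[1])) {
      m <- object@masks[i, , ]
      if (!any(m == 1) || !any(m == 3))
        return("every slice needs non-empty stem and air masks")
    }
    if (object@timeStep <= 0) return("timeStep must be positive")
    TRUE
  })

#' FlowSignalMatrix: baseline-subtracted, air-normalized flow signal
#'
#' Entry \code{[i, t]} is the normalized contrast accumulation of slice i at
#' timepoint t: the stem-mean increase over the first timepoint divided by
#' the concurrent air mean. The first column is identically zero.
#'
#' @slot values numeric matrix \code{[slice, time]}.
#' @slot slicePositions axial slice positions in mm.
#' @slot timeMinutes acquisition times in minutes (first timepoint = 0).
#' @export
setClass("FlowSignalMatrix",
  representation(values = "matrix", slicePositions = "numeric",
                 timeMinutes = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(object@slicePositions) != d[1])
      return("slicePositions must match the number of slices")
    if (length(object@timeMinutes) != d[2])
      return("timeMinutes must match the number of timepoints")
    if (any(!is.finite(object@values)))
      return("flow-signal entries must be finite")
    if (d[2] >= 1 && any(abs(object@values[, 1]) > 0))
      return("first timepoint must be exactly zero (baseline)")
    TRUE
  })

#' DuctGeometry: a rectangular microchannel cross-section
#'
#' @slot width,height cross-section sides in metres.
#' @slot hydraulicDiameter 4 * area / perimeter, metres.
#' @slot aspect height / width ratio (>= 1 by construction).
#' @seealso [ductGeometry()], [rectDuctProfile()]
#' @export
setClass("DuctGeometry",
  representation(width = "numeric", height = "numeric",
                 hydraulicDiameter = "numeric", aspect = "numeric"),
  validity = function(object) {
    if (object@width <= 0 || object@height <= 0)
      return("duct sides must be positive")
    dh <- 4 * object@width * object@height /
      (2 * (object@width + object@height))
    if (abs(object@hydraulicDiameter - dh) > 1e-12 * dh)
      return("hydraulicDiameter inconsistent with sides")
    TRUE
  })

#' FlowConditions: the scalar hydraulic state of a conduit system
#'
#' Bundles volumetric flow Q, total cross-section S, mean velocity U0 = Q/S,
#' kinematic viscosity nu, characteristic (hydraulic) diameter Dh and the
#' Reynolds number Re = U0 Dh / nu, all in SI units.
#'
#' @slot Q m^3/s; \code{S} m^2; \code{U0} m/s; \code{nu} m^2/s; \code{Dh} m;
#'   \code{Re} dimensionless. Unknown entries are NA.
#' @slot S total cross-sectional area (m^2).
#' @slot U0 mean velocity (m/s).
#' @slot nu kinematic viscosity (m^2/s).
#' @slot Dh characteristic size (m).
#' @slot Re Reynolds number.
#' @seealso [flowConditions()]
#' @export
setClass("FlowConditions",
  representation(Q = "numeric", S = "numeric", U0 = "numeric",
                 nu = "numeric", Dh = "numeric", Re = "numeric"),
  validity = function(object) {
    if (!is.na(object@nu) && object@nu <= 0)
      return("kinematic viscosity must be positive")
    if (!is.na(object@Q) && !is.na(object@S) && !is.na(object@U0) &&
        object@S > 0 &&
        abs(object@U0 - object@Q / object@S) >
          1e-9 * max(abs(object@U0), 1e-300))
      return("U0 must equal Q/S when both are given")
    TRUE
  })
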