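#' Accessors for xylemflow containers
#'
#' Small accessor generics following Bioconductor conventions: slot access
#' in user code goes through these, never through `@`.
#'
#' @param object an xylemflow S4 object.
#' @return the corresponding component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameA", function(object) standardGeneric("frameA"))
#' @rdname accessors
#' @export
setGeneric("frameB", function(object) standardGeneric("frameB"))
#' @rdname accessors
#' @export
setGeneric("truthField", function(object) standardGeneric("truthField"))
#' @rdname accessors
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))
#' @rdname accessors
#' @export
setGeneric("gridCoords", function(object) standardGeneric("gridCoords"))
#' @rdname accessors
#' @export
setGeneric("validFlags", function(object) standardGeneric("validFlags"))
#' @rdname accessors
#' @export
setGeneric("snrValues", function(object) standardGeneric("snrValues"))
#' @rdname accessors
#' @export
setGeneric("flowMatrix", function(object) standardGeneric("flowMatrix"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("seriesMasks", function(object) standardGeneric("seriesMasks"))
#' @rdname accessors
#' @export
setGeneric("evalField", function(object, x, y) standardGeneric("evalField"))

#' @rdname accessors
#' @export
setMethod("frameA", "ParticleImagePair", function(object) object@frameA)
#' @rdname accessors
#' @export
setMethod("frameB", "ParticleImagePair", function(object) object@frameB)
#' @rdname accessors
#' @export
setMethod("truthField", "ParticleImagePair", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("truthTable", "VesselPhantom", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("labelImage", "VesselPhantom", function(object) object@labelImage)
#' @rdname accessors
#' @export
setMethod("pixelSize", "VesselPhantom", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("velocities", "VelocityField",
  function(object) list(u = object@u, v = object@v))
#' @rdname accessors
#' @export
setMethod("gridCoords", "VelocityField",
  function(object) list(x = object@x, y = object@y))
#' @rdname accessors
#' @export
setMethod("validFlags", "VelocityField", function(object) object@valid)
#' @rdname accessors
#' @export
setMethod("snrValues", "VelocityField", function(object) object@snr)
#' @rdname accessors
#' @export
setMethod("flowMatrix", "FlowSignalMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("seriesData", "MriSeries", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("seriesMasks", "MriSeries", function(object) object@masks)

#' @rdname accessors
#' @param x,y pixel coordinates at which to evaluate a displacement field.
#' @export
setMethod("evalField", "DisplacementField", function(object, x, y) {
  stopifnot(length(x) == length(y))
  d <- object@fun(as.numeric(x), as.numeric(y))
  if (any(!is.finite(d))) stop("displacement field is non-finite on domain")
  colnames(d) <- c("dx", "dy")
  d
})

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf("DisplacementField '%s' on %g x %g px domain\n",
              object@kind, object@width, object@height))
})

setMethod("show", "ParticleImagePair", function(object) {
  d <- dim(object@frameA)
  cat(sprintf(
    "ParticleImagePair %d x %d px, truth '%s', density %.3g /px^2, seed %d\n",
    d[2], d[1], object@truth@kind, object@params$density, object@seed))
})

setMethod("show", "VelocityField", function(object) {
  cat(sprintf(
    "VelocityField %d x %d nodes (pass %d), %.1f%% valid, calib %g um/px\n",
    length(object@x), length(object@y), object@passIndex,
    100 * mean(object@valid), object@calibration))
})

setMethod("show", "CorrelationPlane", function(object) {
  if (object@valid)
    cat(sprintf(
      "CorrelationPlane lags +/-(%d, %d), peak %.3f at (dy=%d, dx=%d), SNR %.2f\n",
      object@maxLag[1], object@maxLag[2], object@peakValue,
      object@peakLag[1], object@peakLag[2],
      object@peakValue / max(object@secondaryValue, 1e-12)))
  else cat("CorrelationPlane (invalid: flat texture)\n")
})

setMethod("show", "VesselPhantom", function(object) {
  cat(sprintf("VesselPhantom: %d vessels, %d x %d px at %.3g um/px\n",
              nrow(object@truth), ncol(object@labelImage),
              nrow(object@labelImage), object@pixelSize))
})

setMethod("show", "MriSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("MriSeries: %d slices x %d timepoints, %d x %d px, dt %g min\n",
              d[1], d[2], d[4], d[3], object@timeStep))
})

setMethod("show", "FlowSignalMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("FlowSignalMatrix: %d slices x %d timepoints, range [%.3g, %.3g]\n",
              d[1], d[2], min(object@values), max(object@values)))
})

setMethod("show", "DuctGeometry", function(object) {
  cat(sprintf("DuctGeometry %g x %g um, Dh = %g um, aspect 1:%g\n",
              object@width * 1e6, object@height * 1e6,
              object@hydraulicDiameter * 1e6, object@aspect))
})

setMethod("show", "FlowConditions", function(object) {
  cat(sprintf(
    "FlowConditions: Q=%.3g m^3/s, S=%.3g m^2, U0=%.3g m/s, Dh=%.3g m, Re=%.2g\n",
    object@Q, object@S, object@U0, object@Dh, object@Re))
})

setMethod("show", "PivConfig", function(object) {
  cat(sprintf(
    "PivConfig: %dx%d -> %dx%d px (h x w), %d passes, %.0f%% overlap, SNR>=%g, median %dx%d\n",
    object@initialWindow[1], object@initialWindow[2],
    object@finalWindow[1], object@finalWindow[2], object@nPasses,
    100 * object@overlap, object@snrThreshold,
    object@medianRegion[1], object@medianRegion[2]))
})
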