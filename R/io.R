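#' Read and write grayscale image stacks as TIFF
#'
#' TIFF is the raster interchange format of the pipeline: tracer frame
#' pairs, label images and MRI series all reduce to grayscale stacks.
#' Integer rasters round-trip losslessly (8-bit frames are preserved
#' without rescaling; label and 16-bit data use 16 bits per sample).
#'
#' @param path file path.
#' @return \code{readImageStack}: a list of integer-valued matrices.
#' @export
readImageStack <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    storage.mode(p) <- "integer"
    p
  })
}

#' @rdname readImageStack
#' @param stack a matrix or list of integer-valued matrices in
#'   \code{[0, 2^bits)}.
#' @param bits bits per sample (8 or 16; default chosen from the data
#'   range).
#' @export
writeImageStack <- function(stack, path, bits = NULL) {
  if (is.matrix(stack)) stack <- list(stack)
  mx <- max(vapply(stack, max, numeric(1)))
  mn <- min(vapply(stack, min, numeric(1)))
  if (mn < 0 || any(vapply(stack, function(m) any(m != round(m)), logical(1))))
    stop("image stacks must be non-negative integer rasters")
  if (is.null(bits)) bits <- if (mx <= 255) 8L else 16L
  if (mx > 2^bits - 1) stop("values exceed the sample depth")
  tiff::writeTIFF(lapply(stack, function(m) m / (2^bits - 1)), path,
                  bits.per.sample = bits)
  invisible(path)
}

#' Write a particle-image pair with its truth sidecar
#'
#' Frames are written as a two-page TIFF (A then B) and the generating
#' parameters as a JSON sidecar next to it.
#'
#' @param pair a [ParticleImagePair-class].
#' @param path TIFF path; the sidecar takes the same name with
#'   \code{.json}.
#' @export
writeParticlePair <- function(pair, path) {
  writeImageStack(list(frameA(pair), frameB(pair)), path, bits = 8L)
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(kind = pair@truth@kind, fieldParams = pair@truth@params,
         params = pair@params, seed = pair@seed,
         width = ncol(frameA(pair)), height = nrow(frameA(pair))),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a vessel phantom as label TIFF + truth CSV
#'
#' @param phantom a [VesselPhantom-class].
#' @param tiffPath,csvPath output paths.
#' @export
writeVesselPhantom <- function(phantom, tiffPath, csvPath) {
  writeImageStack(labelImage(phantom), tiffPath, bits = 16L)
  utils::write.csv(truthTable(phantom), csvPath, row.names = FALSE)
  invisible(tiffPath)
}

#' Write a velocity field as CSV
#'
#' Long-format CSV with explicit units in the column names:
#' \code{x_px, y_px, u_px, v_px, u_um_s, v_um_s, snr, valid}.
#'
#' @param field a [VelocityField-class].
#' @param path output CSV path.
#' @export
writeVelocityField <- function(field, path) {
  cal <- calibratedVelocities(field)
  g <- expand.grid(yi = seq_along(field@y), xi = seq_along(field@x))
  df <- data.frame(x_px = field@x[g$xi], y_px = field@y[g$yi],
                   u_px = field@u[cbind(g$yi, g$xi)],
                   v_px = field@v[cbind(g$yi, g$xi)],
                   u_um_s = cal$u[cbind(g$yi, g$xi)],
                   v_um_s = cal$v[cbind(g$yi, g$xi)],
                   snr = field@snr[cbind(g$yi, g$xi)],
                   valid = field@valid[cbind(g$yi, g$xi)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a velocity-field CSV back into a VelocityField
#'
#' @param path CSV written by [writeVelocityField()].
#' @param calibration,dt calibration used when writing.
#' @return a [VelocityField-class].
#' @export
readVelocityField <- function(path, calibration = 1, dt = 1) {
  df <- utils::read.csv(path)
  need <- c("x_px", "y_px", "u_px", "v_px", "snr", "valid")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("malformed velocity CSV: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  xs <- sort(unique(df$x_px)); ys <- sort(unique(df$y_px))
  ix <- match(df$x_px, xs); iy <- match(df$y_px, ys)
  mk <- function(vals, default = NA_real_) {
    m <- matrix(default, length(ys), length(xs))
    m[cbind(iy, ix)] <- vals
    m
  }
  new("VelocityField", x = xs, y = ys, u = mk(df$u_px), v = mk(df$v_px),
      snr = mk(df$snr), valid = mk(as.logical(df$valid), FALSE),
      replaced = matrix(FALSE, length(ys), length(xs)),
      passIndex = 0L, calibration = calibration, dt = dt)
}

#' Write an MRI series as TIFF stack + masks + truth JSON
#'
#' Intensities are written slice-major (all timepoints of slice 1, then
#' slice 2, ...), masks as one page per slice, truth as JSON.
#'
#' @param series an [MriSeries-class].
#' @param dir output directory (created).
#' @export
writeMriSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series@data)
  pages <- list()
  for (i in seq_len(d[1])) for (t in seq_len(d[2]))
    pages[[length(pages) + 1]] <- quantize16(series@data[i, t, , ])
  writeImageStack(pages, file.path(dir, "series.tiff"), bits = 16L)
  writeImageStack(lapply(seq_len(d[1]), function(i) series@masks[i, , ]),
                  file.path(dir, "masks.tiff"), bits = 8L)
  jsonlite::write_json(
    c(list(nSlices = d[1], nTimes = d[2], timeStep = series@timeStep,
           sliceSpacing = series@sliceSpacing), series@truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

quantize16 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 65535] <- 65535
  m
}
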