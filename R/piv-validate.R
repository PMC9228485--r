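#' Signal-to-noise-ratio vector validation
#'
#' Flags every node whose primary/secondary correlation peak ratio falls
#' below the threshold. Idempotent: the SNR values are not altered.
#'
#' @param field a [VelocityField-class] carrying per-node SNR.
#' @param threshold minimum acceptable peak ratio (default 2).
#' @return the field with updated validity flags.
#' @export
validateSnr <- function(field, threshold = 2) {
  stopifnot(is(field, "VelocityField"))
  bad <- !is.na(field@snr) & field@snr < threshold
  bad[is.na(field@snr)] <- TRUE
  field@valid <- field@valid & !bad
  validObject(field)
  field
}

#' Adaptive (normalized) median vector validation
#'
#' The field-standard reading of adaptive median filtering: for each node,
#' each velocity component is compared to the median of the valid neighbors
#' in the region through a normalized residual
#' \eqn{r^* = |d - d_m| / (r_m + \epsilon)}, where \eqn{d_m} is the
#' neighborhood median, \eqn{r_m} the median of the neighbors' own
#' residuals and \eqn{\epsilon = 0.1} px a noise stabilizer. Nodes with
#' \eqn{r^* >} \code{threshold} on either component are flagged invalid, and
#' every invalid node (from this test or an earlier stage) is replaced by
#' the valid-neighbor median. Border nodes use truncated neighborhoods.
#' Applying the test twice gives the same field as applying it once.
#'
#' @param field a [VelocityField-class].
#' @param region odd \code{c(h, w)} neighborhood in grid nodes (default 7x7).
#' @param threshold normalized-residual threshold (default 2).
#' @param eps stabilizer in px (default 0.1).
#' @return the validated field; replaced nodes have \code{replaced = TRUE}.
#' @export
validateAdaptiveMedian <- function(field, region = c(7, 7), threshold = 2,
                                   eps = 0.1) {
  stopifnot(is(field, "VelocityField"))
  region <- as.integer(region)
  if (any(region %% 2 != 1)) stop("region must be odd in both dimensions")
  ny <- length(field@y); nx <- length(field@x)
  if (region[1] > ny || region[2] > nx)
    stop("median region larger than the vector grid")
  hy <- region[1] %/% 2; hx <- region[2] %/% 2
  u <- field@u; v <- field@v; valid <- field@valid
  outlier <- matrix(FALSE, ny, nx)
  medU <- matrix(NA_real_, ny, nx); medV <- matrix(NA_real_, ny, nx)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      ri <- max(1, i - hy):min(ny, i + hy)
      rj <- max(1, j - hx):min(nx, j + hx)
      nb <- valid[ri, rj, drop = FALSE]
      nb[match(i, ri) + (match(j, rj) - 1) * length(ri)] <- FALSE  # exclude self
      if (!any(nb)) next
      nu <- u[ri, rj, drop = FALSE][nb]
      nv <- v[ri, rj, drop = FALSE][nb]
      mu <- stats::median(nu); mv <- stats::median(nv)
      medU[i, j] <- mu; medV[i, j] <- mv
      if (valid[i, j]) {
        rmu <- stats::median(abs(nu - mu))
        rmv <- stats::median(abs(nv - mv))
        if (abs(u[i, j] - mu) / (rmu + eps) > threshold ||
            abs(v[i, j] - mv) / (rmv + eps) > threshold)
          outlier[i, j] <- TRUE
      }
    }
  }
  valid[outlier] <- FALSE
  toReplace <- !valid & !is.na(medU)
  u[toReplace] <- medU[toReplace]
  v[toReplace] <- medV[toReplace]
  field@u <- u; field@v <- v; field@valid <- valid
  field@replaced <- field@replaced | toReplace
  validObject(field)
  field
}

#' Ensemble-average instantaneous velocity fields
#'
#' Per-node mean over the fields in which the node is valid; a node is valid
#' in the output only if it was valid in at least half of the inputs (the
#' ensemble analogue of averaging thousands of instantaneous fields into one
#' mean-current field).
#'
#' @param fields a non-empty list of [VelocityField-class] on identical grids.
#' @return the ensemble-mean [VelocityField-class].
#' @export
ensembleAverage <- function(fields) {
  if (!length(fields)) stop("need at least one field")
  f1 <- fields[[1]]
  for (f in fields)
    if (!identical(f@x, f1@x) || !identical(f@y, f1@y))
      stop("fields must share an identical grid")
  dims <- dim(f1@u)
  su <- sv <- ss <- matrix(0, dims[1], dims[2])
  cnt <- matrix(0L, dims[1], dims[2])
  for (f in fields) {
    w <- f@valid
    su <- su + ifelse(w, f@u, 0)
    sv <- sv + ifelse(w, f@v, 0)
    ss <- ss + ifelse(w & is.finite(f@snr), f@snr, 0)
    cnt <- cnt + w
  }
  ok <- cnt >= length(fields) / 2 & cnt > 0
  u <- ifelse(cnt > 0, su / pmax(cnt, 1), 0)
  v <- ifelse(cnt > 0, sv / pmax(cnt, 1), 0)
  snr <- ifelse(cnt > 0, ss / pmax(cnt, 1), NA_real_)
  new("VelocityField", x = f1@x, y = f1@y, u = u, v = v, snr = snr,
      valid = ok, replaced = matrix(FALSE, dims[1], dims[2]),
      passIndex = f1@passIndex, calibration = f1@calibration, dt = f1@dt)
}
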