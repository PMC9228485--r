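# Multipass window-deformation PIV.

# Window sizes per pass: geometric interpolation between the initial and
# final window, forced even so half-window grids stay integral.
passWindows <- function(cfg) {
  n <- cfg@nPasses
  if (n == 1) return(list(cfg@finalWindow))
  lapply(seq_len(n), function(p) {
    f <- (p - 1) / (n - 1)
    s <- round(cfg@initialWindow * (cfg@finalWindow / cfg@initialWindow)^f)
    as.integer(pmax(4, 2 * round(s / 2)))
  })
}

# Regular interrogation grid: window centers half a window from the border,
# spaced by window * (1 - overlap).
windowGrid <- function(H, W, win, overlap) {
  stepY <- max(1, round(win[1] * (1 - overlap)))
  stepX <- max(1, round(win[2] * (1 - overlap)))
  cy <- seq(win[1] / 2, H - win[1] / 2, by = stepY)
  cx <- seq(win[2] / 2, W - win[2] / 2, by = stepX)
  list(x = cx, y = cy)
}

boxSmooth3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    out[i, j] <- mean(m[max(1, i - 1):min(ny, i + 1),
                        max(1, j - 1):min(nx, j + 1)])
  }
  out
}

#' Multipass window-deformation PIV
#'
#' Computes the instantaneous velocity field of a particle-image pair by
#' iterative cross-correlation with window refinement and image deformation.
#' Each pass interrogates zero-normalized windows on a regular grid, refines
#' the correlation peak with the three-point Gaussian estimator, validates
#' vectors by SNR and the normalized median test, then deforms frame B
#' toward frame A with the bilinearly densified, lightly smoothed predictor
#' field before the next (finer) pass. The final grid has spacing
#' \code{finalWindow * (1 - overlap)}.
#'
#' @param pair a [ParticleImagePair-class] (or any object with frame
#'   accessors); frames must fit at least one initial window.
#' @param cfg a [PivConfig-class].
#' @param maxInvalidFraction error if more than this fraction of final-pass
#'   vectors is invalid (default 0.5), which signals a seeding or contrast
#'   failure rather than a flow measurement.
#' @return the final-pass [VelocityField-class]; displacements in px/frame.
#' @examples
#' pair <- makeParticleImagePair(uniformField(3, 0, 192, 64), seed = 4)
#' fld <- multipassPiv(pair, pivConfig())
#' mean(velocities(fld)$u[validFlags(fld)])
#' @export
multipassPiv <- function(pair, cfg = pivConfig(), maxInvalidFraction = 0.5) {
  a <- frameA(pair); b <- frameB(pair)
  H <- nrow(a); W <- ncol(a)
  if (H < cfg@initialWindow[1] || W < cfg@initialWindow[2])
    stop("image smaller than one initial interrogation window")
  wins <- passWindows(cfg)
  predU <- predV <- NULL   # dense predictor maps, px
  field <- NULL
  for (p in seq_len(cfg@nPasses)) {
    win <- wins[[p]]
    g <- windowGrid(H, W, win, cfg@overlap)
    bw <- if (is.null(predU)) b else cpp_warp_bicubic(b, predU, predV)
    ny <- length(g$y); nx <- length(g$x)
    u <- v <- snr <- matrix(NA_real_, ny, nx)
    valid <- matrix(TRUE, ny, nx)
    maxLag <- as.integer(win %/% 2)
    for (j in seq_len(nx)) {
      cols <- (g$x[j] - win[2] / 2 + 1):(g$x[j] + win[2] / 2)
      for (i in seq_len(ny)) {
        rows <- (g$y[i] - win[1] / 2 + 1):(g$y[i] + win[1] / 2)
        wa <- a[rows, cols]; wb <- bw[rows, cols]
        pU <- if (is.null(predU)) 0 else mean(predU[rows, cols])
        pV <- if (is.null(predV)) 0 else mean(predV[rows, cols])
        plane <- correlateWindow(wa, wb, maxLag)
        if (!plane@valid) { valid[i, j] <- FALSE; u[i, j] <- pU; v[i, j] <- pV; next }
        snr[i, j] <- plane@peakValue / max(plane@secondaryValue, 1e-12)
        interior <- all(abs(plane@peakLag) < maxLag)
        if (interior) {
          sp <- subpixelPeak(plane)
          u[i, j] <- pU + sp$lag[2]
          v[i, j] <- pV + sp$lag[1]
        } else {
          # peak on the search border: integer estimate only, mark invalid
          u[i, j] <- pU + plane@peakLag[2]
          v[i, j] <- pV + plane@peakLag[1]
          valid[i, j] <- FALSE
        }
      }
    }
    field <- new("VelocityField", x = g$x, y = g$y, u = u, v = v,
                 snr = snr, valid = valid,
                 replaced = matrix(FALSE, ny, nx), passIndex = as.integer(p),
                 calibration = cfg@calibration, dt = cfg@dt)
    field <- validateSnr(field, cfg@snrThreshold)
    region <- pmin(cfg@medianRegion, c(ny, nx))
    region <- region - (1 - region %% 2)  # largest odd region fitting the grid
    field <- validateAdaptiveMedian(field, region = region)
    # any node still lacking a usable value falls back to the predictor mean
    nas <- !is.finite(field@u) | !is.finite(field@v)
    field@u[nas] <- 0; field@v[nas] <- 0
    if (p < cfg@nPasses) {
      su <- boxSmooth3(field@u); sv <- boxSmooth3(field@v)
      predU <- cpp_densify_bilinear(g$x, g$y, su, H, W)
      predV <- cpp_densify_bilinear(g$x, g$y, sv, H, W)
    }
  }
  if (mean(!field@valid) > maxInvalidFraction)
    stop(sprintf(
      "%.0f%% of final-pass vectors invalid: seeding or contrast failure",
      100 * mean(!field@valid)))
  field
}

#' Calibrated velocities of a field
#'
#' @param field a [VelocityField-class].
#' @return list of matrices \code{u, v} in micrometres per second
#'   (px/frame * calibration / dt).
#' @export
calibratedVelocities <- function(field) {
  k <- field@calibration / field@dt
  list(u = field@u * k, v = field@v * k)
}

#' Extract a transverse velocity profile at a station
#'
#' Returns the longitudinal velocity component against the transverse
#' coordinate at a given downstream station, linearly interpolated between
#' the two bracketing grid columns, optionally normalized by a reference
#' mean velocity U0 (the profile form in which merging-channel measurements
#' are reported).
#'
#' @param field a [VelocityField-class].
#' @param stationX station in micrometres from the left image edge.
#' @param U0 optional reference velocity in um/s for the \code{U_over_U0}
#'   column.
#' @return data.frame with \code{y_um}, \code{u_um_s} and (if U0 given)
#'   \code{U_over_U0}; invalid nodes are dropped.
#' @export
extractProfile <- function(field, stationX, U0 = NULL) {
  xum <- field@x * field@calibration
  if (stationX < min(xum) || stationX > max(xum))
    stop("station outside the field extent")
  j1 <- max(which(xum <= stationX))
  j2 <- min(which(xum >= stationX))
  w <- if (j1 == j2) 0 else (stationX - xum[j1]) / (xum[j2] - xum[j1])
  cal <- calibratedVelocities(field)
  u <- (1 - w) * cal$u[, j1] + w * cal$u[, j2]
  ok <- field@valid[, j1] & field@valid[, j2]
  out <- data.frame(y_um = field@y[ok] * field@calibration, u_um_s = u[ok])
  if (!is.null(U0)) out$U_over_U0 <- out$u_um_s / U0
  out
}
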