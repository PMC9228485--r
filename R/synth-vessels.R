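#' Generate a labeled vessel cross-section phantom
#'
#' Rasterizes non-overlapping ellipses ("vessel lumina") at polar positions
#' around the image center, arranged in concentric rings the way metaxylem
#' vessels sit in rings of vascular bundles in a grass stem cross section.
#' Labels are consecutive positive integers and correspond one-to-one to the
#' rows of the ground-truth table.
#'
#' @param ringSpec data.frame with one row per ring: \code{radius} (px),
#'   \code{count}, \code{aMin}, \code{aMax} (semi-major axis range, px),
#'   \code{ratioMin} (minimum semi-minor/semi-major ratio). Default: four
#'   rings at radii 100/200/300/400 px.
#' @param imageSize image side in px (square raster); default large enough
#'   for the default rings.
#' @param pixelSize micrometres per pixel (default 0.692, the optical-section
#'   resolution of the laser scanning microscope).
#' @param seed integer seed; identical seeds reproduce the label image
#'   bit-exactly.
#' @param maxTries placement retries per vessel before failing with an
#'   overlap report.
#' @return a [VesselPhantom-class] with truth columns \code{label, cx_px,
#'   cy_px, a_px, b_px, theta_rad, ring}.
#' @examples
#' ph <- makeVesselPhantom(seed = 7)
#' ph
#' @export
makeVesselPhantom <- function(ringSpec = defaultRingSpec(), imageSize = 900,
                              pixelSize = 0.692, seed = 1, maxTries = 100) {
  stopifnot(is.data.frame(ringSpec),
            all(c("radius", "count", "aMin", "aMax", "ratioMin")
                %in% names(ringSpec)))
  cx0 <- imageSize / 2
  cy0 <- imageSize / 2
  withSeed(seed, {
    rows <- list()
    placed <- matrix(numeric(0), ncol = 3)  # cx, cy, bounding radius
    romans <- c("I", "II", "III", "IV")
    for (k in seq_len(nrow(ringSpec))) {
      rs <- ringSpec[k, ]
      base <- seq(0, 2 * pi, length.out = rs$count + 1)[-(rs$count + 1)]
      for (j in seq_len(rs$count)) {
        ok <- FALSE
        for (try in seq_len(maxTries)) {
          ang <- base[j] + stats::runif(1, -0.4, 0.4) * 2 * pi / rs$count
          a <- stats::runif(1, rs$aMin, rs$aMax)
          b <- a * stats::runif(1, rs$ratioMin, 1)
          th <- stats::runif(1, 0, pi)
          cx <- cx0 + rs$radius * cos(ang)
          cy <- cy0 + rs$radius * sin(ang)
          rb <- a + 2
          clear <- nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  placed[, 3] + rb)
          if (clear) {
            placed <- rbind(placed, c(cx, cy, rb))
            rows[[length(rows) + 1]] <- data.frame(
              cx_px = cx, cy_px = cy, a_px = a, b_px = b, theta_rad = th,
              ring = romans[min(k, 4)])
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop(sprintf(
            "could not place vessel %d of ring %d without overlap after %d tries",
            j, k, maxTries))
      }
    }
    truth <- do.call(rbind, rows)
    truth <- cbind(label = seq_len(nrow(truth)), truth)
    lab <- matrix(0L, imageSize, imageSize)
    for (i in seq_len(nrow(truth))) {
      lab <- rasterizeEllipse(lab, i, truth$cx_px[i], truth$cy_px[i],
                              truth$a_px[i], truth$b_px[i],
                              truth$theta_rad[i])
    }
    new("VesselPhantom", labelImage = lab, truth = truth,
        pixelSize = pixelSize)
  })
}

#' @rdname makeVesselPhantom
#' @export
defaultRingSpec <- function() {
  data.frame(radius = c(100, 200, 300, 400),
             count = c(8, 12, 16, 20),
             aMin = c(8, 10, 12, 14),
             aMax = c(18, 22, 25, 28),
             ratioMin = rep(0.6, 4))
}

# Stamp one filled ellipse into an integer label raster. Pixel (r, c)
# (0-based) has center (c + 0.5, r + 0.5) px; a pixel belongs to the ellipse
# if its center lies inside.
rasterizeEllipse <- function(lab, label, cx, cy, a, b, theta) {
  n <- nrow(lab)
  rmax <- max(a, b)
  c0 <- max(1, floor(cx - rmax)); c1 <- min(ncol(lab), ceiling(cx + rmax) + 1)
  r0 <- max(1, floor(cy - rmax)); r1 <- min(n, ceiling(cy + rmax) + 1)
  cc <- (c0:c1) - 0.5
  rr <- (r0:r1) - 0.5
  dx <- outer(rep(1, length(rr)), cc - cx)
  dy <- outer(rr - cy, rep(1, length(cc)))
  xr <- (dx * cos(theta) + dy * sin(theta)) / a
  yr <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- xr^2 + yr^2 <= 1
  sub <- lab[r0:r1, c0:c1]
  sub[inside] <- as.integer(label)
  lab[r0:r1, c0:c1] <- sub
  lab
}
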