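#' Per-vessel geometry from a labeled cross-section image
#'
#' Measures every labeled region of a vessel cross-section raster: area
#' (pixel count), perimeter (Crofton 4-direction estimator — a
#' boundary-pixel count would overestimate the perimeter of smooth lumina by
#' up to ~27\% and correspondingly bias the hydraulic diameter low),
#' centroid, moment-based ellipse fit and hydraulic diameter Dh = 4S/P.
#' Holes inside a lumen are filled before measurement, since the lumen is
#' the hydraulic cross-section. Physical coordinates use the pixel-center
#' convention \code{(index + 0.5) * pixel_size} with x rightward and y
#' downward.
#'
#' @param labels integer label matrix (0 = background) or a
#'   [VesselPhantom-class].
#' @param pixelSize micrometres per pixel (default 0.692, the LSM
#'   optical-section resolution; ignored when a phantom carries its own).
#' @param fillHoles fill interior holes before measuring (default TRUE).
#' @return data.frame with one row per label: \code{label, S_um2, P_um,
#'   Dh_um, cx_um, cy_um, a_um, b_um, theta_rad}.
#' @examples
#' ph <- makeVesselPhantom(seed = 3)
#' head(measureLabels(ph))
#' @export
measureLabels <- function(labels, pixelSize = 0.692, fillHoles = TRUE) {
  if (is(labels, "VesselPhantom")) {
    pixelSize <- labels@pixelSize
    labels <- labels@labelImage
  }
  if (!is.matrix(labels) || any(labels != round(labels)))
    stop("labels must be an integer raster")
  if (pixelSize <= 0) stop("pixelSize must be positive")
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  if (!length(ids)) stop("label image contains no regions")
  rows <- lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 1); r1 <- min(nrow(labels), max(idx[, 1]) + 1)
    c0 <- max(1, min(idx[, 2]) - 1); c1 <- min(ncol(labels), max(idx[, 2]) + 1)
    m <- labels[r0:r1, c0:c1] == id
    if (fillHoles)
      m <- EBImage::fillHull(m) > 0
    S <- sum(m) * pixelSize^2
    P <- croftonPerimeter(m) * pixelSize
    # pixel-center coordinates in the full image frame, 0-based indices
    pr <- which(m, arr.ind = TRUE)
    ys <- (pr[, 1] + r0 - 1 - 0.5)  # (row index - 1) + 0.5
    xs <- (pr[, 2] + c0 - 1 - 0.5)
    ell <- momentEllipse(xs, ys)
    data.frame(label = id, S_um2 = S, P_um = P, Dh_um = 4 * S / P,
               cx_um = mean(xs) * pixelSize, cy_um = mean(ys) * pixelSize,
               a_um = ell$a * pixelSize, b_um = ell$b * pixelSize,
               theta_rad = ell$theta)
  })
  do.call(rbind, rows)
}

# Crofton 4-direction perimeter of a logical mask, in pixel units.
# For each direction the boundary length estimate is pi * (number of runs
# along the direction's grid lines) * (line spacing); the four estimates
# (0, 90, 45, 135 degrees; diagonal spacing 1/sqrt(2)) are averaged.
croftonPerimeter <- function(m) {
  m <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)  # pad so runs terminate
  nr <- nrow(m); nc <- ncol(m)
  runsH <- sum(m[, -1] & !m[, -nc])                   # horizontal runs
  runsV <- sum(m[-1, ] & !m[-nr, ])                   # vertical runs
  runsD1 <- sum(m[-1, -1] & !m[-nr, -nc])             # 135-degree lines
  runsD2 <- sum(m[-1, -nc] & !m[-nr, -1])             # 45-degree lines
  (pi / 4) * (runsH + runsV + (runsD1 + runsD2) / sqrt(2))
}

# Moment-based ellipse: semi-axes from the eigenvalues of the second central
# moment matrix of the pixel centers (a = 2*sqrt(lambda_max)), orientation of
# the major axis in [0, pi).
momentEllipse <- function(xs, ys) {
  if (length(xs) < 5) stop("region too small for an ellipse fit (< 5 px)")
  mx <- mean(xs); my <- mean(ys)
  # + 1/12: second moment of the unit pixel itself
  mu20 <- mean((xs - mx)^2) + 1 / 12
  mu02 <- mean((ys - my)^2) + 1 / 12
  mu11 <- mean((xs - mx) * (ys - my))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) stop("degenerate (collinear) region")
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(a = 2 * sqrt(l1), b = 2 * sqrt(l2), theta = theta %% pi)
}

#' Hydraulic diameter of a conduit cross-section
#'
#' \eqn{D_h = 4S/P}, the characteristic size of a non-circular conduit: for
#' a circle it equals the diameter, for a square duct the side, and for a
#' 120 x 240 um rectangular channel 160 um.
#'
#' @param S cross-sectional area (any area unit).
#' @param P perimeter (the matching length unit).
#' @return Dh in the length unit of \code{P}.
#' @examples
#' hydraulicDiameter(120 * 240, 2 * (120 + 240))  # 160
#' @export
hydraulicDiameter <- function(S, P) {
  if (any(S <= 0) || any(P <= 0)) stop("S and P must be positive")
  4 * S / P
}

#' Fit a moment ellipse to one labeled region
#'
#' @param labels integer label matrix or [VesselPhantom-class].
#' @param id label to fit.
#' @param pixelSize micrometres per pixel.
#' @return list with semi-axes \code{a, b} (um) and \code{theta} (rad, major
#'   axis, in [0, pi)).
#' @export
fitEllipse <- function(labels, id, pixelSize = 0.692) {
  if (is(labels, "VesselPhantom")) {
    pixelSize <- labels@pixelSize
    labels <- labels@labelImage
  }
  idx <- which(labels == id, arr.ind = TRUE)
  if (!nrow(idx)) stop("no such label")
  ell <- momentEllipse(idx[, 2] - 0.5, idx[, 1] - 0.5)
  list(a = ell$a * pixelSize, b = ell$b * pixelSize, theta = ell$theta)
}

#' Assign concentric ring membership in polar coordinates
#'
#' Recalculates vessel centroids into a polar system about the nominal stem
#' center (by default the centroid of all vessel centroids) and assigns
#' rings I-IV by radius: against explicit edges when given, otherwise by
#' radius quartile breaks. With quantile breaks, ties collapse toward the
#' innermost ring.
#'
#' @param records data.frame from [measureLabels()] (needs \code{cx_um,
#'   cy_um}).
#' @param center optional explicit \code{c(x, y)} stem center in um.
#' @param ringEdges optional increasing radii (um) separating rings I|II,
#'   II|III, III|IV.
#' @return the records with added \code{r_um, theta_rad_polar, ring}.
#' @export
assignRings <- function(records, center = NULL, ringEdges = NULL) {
  stopifnot(all(c("cx_um", "cy_um") %in% names(records)))
  if (is.null(center))
    center <- c(mean(records$cx_um), mean(records$cy_um))
  dx <- records$cx_um - center[1]
  dy <- records$cy_um - center[2]
  r <- sqrt(dx^2 + dy^2)
  romans <- c("I", "II", "III", "IV")
  if (is.null(ringEdges)) {
    if (nrow(records) < 4)
      stop("need >= 4 records for quantile ring edges; give ringEdges")
    ringEdges <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
  }
  if (length(ringEdges) != 3 || is.unsorted(ringEdges))
    stop("ringEdges must be three increasing radii")
  ring <- romans[findInterval(r, ringEdges, left.open = TRUE) + 1]
  records$r_um <- r
  records$theta_rad_polar <- atan2(dy, dx)
  records$ring <- ring
  records
}

#' Attach per-vessel Reynolds numbers
#'
#' \eqn{Re = U_0 D_h / \nu} with the mean xylem flow velocity as the
#' velocity scale and each vessel's hydraulic diameter as its
#' characteristic size; inputs are converted to SI before dividing.
#'
#' @param records data.frame with a \code{Dh_um} column.
#' @param U0 mean flow velocity in micrometres per second (default 221.5,
#'   the mean xylem velocity implied by transpiration flux over total xylem
#'   area in a young maize stem).
#' @param nu kinematic viscosity in m^2/s (default 8.74e-7, water at 26 C).
#' @return records with an added \code{Re} column.
#' @export
reynoldsPerVessel <- function(records, U0 = 221.5, nu = 8.74e-7) {
  if (!"Dh_um" %in% names(records)) stop("records lack Dh_um")
  if (U0 <= 0 || nu <= 0) stop("U0 and nu must be positive")
  records$Re <- umToM(U0) * umToM(records$Dh_um) / nu
  records
}

#' Stem-level morphometry summary
#'
#' @param records ring-assigned records (from [assignRings()], optionally
#'   with Re).
#' @return list with \code{center_um}, \code{totalArea_um2}, and a per-ring
#'   data.frame of counts, area totals and Re quantiles (2.5/25/50/75/97.5\%,
#'   the numbers a violin plot summarizes).
#' @export
summarizeStem <- function(records) {
  if (!nrow(records)) stop("no records")
  hasRing <- "ring" %in% names(records)
  hasRe <- "Re" %in% names(records)
  perRing <- NULL
  if (hasRing) {
    perRing <- do.call(rbind, lapply(split(records, records$ring), function(d) {
      out <- data.frame(ring = d$ring[1], n = nrow(d),
                        totalArea_um2 = sum(d$S_um2))
      if (hasRe) {
        q <- stats::quantile(d$Re, c(0.025, 0.25, 0.5, 0.75, 0.975),
                             names = FALSE)
        out <- cbind(out, data.frame(Re_q025 = q[1], Re_q25 = q[2],
                                     Re_med = q[3], Re_q75 = q[4],
                                     Re_q975 = q[5]))
      }
      out
    }))
    rownames(perRing) <- NULL
  }
  list(center_um = c(mean(records$cx_um), mean(records$cy_um)),
       totalArea_um2 = sum(records$S_um2),
       nVessels = nrow(records),
       perRing = perRing)
}

#' Full morphometry pipeline on a label image
#'
#' Convenience wrapper: measure, assign rings, attach Re, summarize.
#'
#' @inheritParams measureLabels
#' @inheritParams assignRings
#' @inheritParams reynoldsPerVessel
#' @return list with \code{records} and \code{summary}.
#' @export
vesselMorphometry <- function(labels, pixelSize = 0.692, center = NULL,
                              ringEdges = NULL, U0 = 221.5, nu = 8.74e-7) {
  rec <- measureLabels(labels, pixelSize)
  rec <- assignRings(rec, center = center, ringEdges = ringEdges)
  rec <- reynoldsPerVessel(rec, U0 = U0, nu = nu)
  list(records = rec, summary = summarizeStem(rec))
}
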