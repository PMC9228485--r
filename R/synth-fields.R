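#' Prescribed displacement fields
#'
#' Constructors for the ground-truth motions used by the synthetic
#' particle-image generator: a spatially uniform translation, a plane
#' Poiseuille (parabolic) channel profile with walls on the top and bottom
#' image edges, and an analytic Y-junction merge model.
#'
#' @param dx,dy uniform displacement components in px/frame.
#' @param width,height domain size in px.
#' @return a [DisplacementField-class].
#' @examples
#' f <- uniformField(3, 0, 192, 64)
#' evalField(f, c(10, 50), c(5, 20))
#' @export
uniformField <- function(dx, dy, width, height) {
  stopifnot(is.finite(dx), is.finite(dy))
  new("DisplacementField",
      fun = function(x, y) cbind(rep(dx, length(x)), rep(dy, length(x))),
      width = width, height = height, kind = "uniform",
      params = list(dx = dx, dy = dy))
}

#' @rdname uniformField
#' @param uMax centerline (maximum) longitudinal velocity in px/frame. The
#'   longitudinal component vanishes on the walls y = 0 and y = height and
#'   peaks on the centerline; the transverse component is zero.
#' @export
poiseuilleField <- function(uMax, width, height) {
  stopifnot(uMax >= 0)
  h2 <- height / 2
  new("DisplacementField",
      fun = function(x, y) {
        xi <- (y - h2) / h2
        u <- uMax * pmax(0, 1 - xi^2)
        cbind(u, rep(0, length(x)))
      },
      width = width, height = height, kind = "poiseuille",
      params = list(uMax = uMax))
}

#' Analytic Y-junction merge displacement field
#'
#' An exactly divergence-free analytic stand-in (not a Navier-Stokes
#' solution) for two parabolic inlet streams merging into one duct. At the
#' junction (x = 0) the lower half-channel (y < height/2) carries the
#' inlet-1 flux share 1/(1+R) and the upper half the inlet-2 share R/(1+R),
#' each as a parabola over its half; the profiles relax exponentially over
#' the development length to the fully developed single-duct parabola. The
#' longitudinal integral of u across the channel equals mean_speed * height
#' at every station, so station-to-station flux is conserved exactly; the
#' transverse component is derived from continuity and vanishes on both
#' walls.
#'
#' @param ratioR inlet flow-rate ratio R = Q2/Q1 in (0, 1]; inlet 1 (the
#'   higher-flux stream) occupies the lower half of the channel.
#' @param meanSpeed cross-section mean longitudinal speed, px/frame.
#' @param width,height domain size in px.
#' @param devLength exponential development length in px (default 800,
#'   the scale over which merging profiles relax in micro-channel flows of
#'   this regime).
#' @return a [DisplacementField-class] of kind \code{"y-merge"}.
#' @export
yMergeField <- function(ratioR, meanSpeed, width, height, devLength = 800) {
  if (!is.numeric(ratioR) || length(ratioR) != 1 || ratioR <= 0 || ratioR > 1)
    stop("ratioR must lie in (0, 1]")
  stopifnot(meanSpeed >= 0, devLength > 0)
  H <- height
  U <- meanSpeed
  s1 <- 1 / (1 + ratioR)   # flux share of inlet 1 (lower half)
  s2 <- ratioR / (1 + ratioR)

  # Inlet composite: parabola on [0, H/2] with mean 2*s1*U, parabola on
  # [H/2, H] with mean 2*s2*U. Fully developed: parabola on [0, H], mean U.
  uIn <- function(y) {
    lower <- y < H / 2
    xi <- ifelse(lower, (y - H / 4) / (H / 4), (y - 3 * H / 4) / (H / 4))
    m <- ifelse(lower, 2 * s1 * U, 2 * s2 * U)
    1.5 * m * pmax(0, 1 - xi^2)
  }
  uOut <- function(y) {
    xi <- (y - H / 2) / (H / 2)
    1.5 * U * pmax(0, 1 - xi^2)
  }
  # Antiderivative in y of (uOut - uIn), zero at y = 0 and y = H.
  intDiff <- function(y) {
    y <- pmin(pmax(y, 0), H)
    iOut <- 1.5 * U * (y - (4 / (3 * H^2)) * (y - H / 2)^3) -
      1.5 * U * (0 - (4 / (3 * H^2)) * (-H / 2)^3)
    prim <- function(y, c0, m) {
      # integral of half-channel parabola (center c0, half-width H/4, mean m)
      # from its own lower wall to y, y clamped to the half interval
      a <- c0 - H / 4; b <- c0 + H / 4
      y <- pmin(pmax(y, a), b)
      1.5 * m * ((y - c0) - (16 / (3 * H^2)) * (y - c0)^3) -
        1.5 * m * ((a - c0) - (16 / (3 * H^2)) * (a - c0)^3)
    }
    iIn <- prim(y, H / 4, 2 * s1 * U) +
      ifelse(y > H / 2, prim(y, 3 * H / 4, 2 * s2 * U), 0)
    iOut - iIn
  }
  new("DisplacementField",
      fun = function(x, y) {
        w <- 1 - exp(-pmax(x, 0) / devLength)
        dw <- exp(-pmax(x, 0) / devLength) / devLength
        u <- (1 - w) * uIn(y) + w * uOut(y)
        v <- -dw * intDiff(y)
        cbind(u, v)
      },
      width = width, height = height, kind = "y-merge",
      params = list(ratioR = ratioR, meanSpeed = meanSpeed,
                    devLength = devLength))
}

#' Integrated longitudinal flux of a displacement field at a station
#'
#' Trapezoidal quadrature of the longitudinal component across the channel
#' at a fixed x; used to check station-to-station flux conservation of
#' merge fields.
#'
#' @param field a [DisplacementField-class].
#' @param stationX station in px.
#' @param n number of quadrature points.
#' @return flux in px^2/frame.
#' @export
fieldFlux <- function(field, stationX, n = 401) {
  y <- seq(0, field@height, length.out = n)
  u <- evalField(field, rep(stationX, n), y)[, "dx"]
  sum((u[-1] + u[-n]) / 2) * (field@height / (n - 1))
}
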