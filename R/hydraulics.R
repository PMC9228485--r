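#' Rectangular duct geometry
#'
#' @param width,height cross-section sides in micrometres (defaults
#'   120 x 240, the Y-junction chip outlet; the inlets are 120 x 120).
#' @return a [DuctGeometry-class] (SI units internally).
#' @examples
#' ductGeometry()  # Dh = 160 um
#' @export
ductGeometry <- function(width = 120, height = 240) {
  w <- umToM(width); h <- umToM(height)
  new("DuctGeometry", width = w, height = h,
      hydraulicDiameter = 4 * w * h / (2 * (w + h)),
      aspect = max(w, h) / min(w, h))
}

#' Mean flow velocity from volumetric flow and cross-section
#'
#' \eqn{U_0 = Q / S}: the transpiration-driven volumetric flow through the
#' plant divided by the total cross-sectional area of all conducting xylem
#' vessels gives the mean xylem sap velocity.
#'
#' @param Q volumetric flow in m^3/s (>= 0).
#' @param S total cross-sectional area in m^2 (> 0).
#' @return U0 in m/s.
#' @export
meanVelocity <- function(Q, S) {
  if (any(S <= 0)) stop("cross-sectional area must be positive")
  if (any(Q < 0)) stop("volumetric flow must be non-negative")
  Q / S
}

#' Reynolds number
#'
#' \eqn{Re = U_0 D_h / \nu}, the ratio of inertial to viscous forces; the
#' similarity criterion that transfers xylem-vessel flow regimes onto chip
#' microchannels. Inputs are SI; magnitudes that look like micrometre values
#' passed as metres trigger a warning rather than a silent mis-scale.
#'
#' @param U0 mean velocity (m/s).
#' @param Dh characteristic (hydraulic) diameter (m); 0 allowed, giving 0.
#' @param nu kinematic viscosity (m^2/s), default 8.74e-7 (water at 26 C).
#' @return dimensionless Re.
#' @examples
#' reynolds(221.5e-6, 46e-6)   # ~ 0.012
#' reynolds(221.5e-6, 3.8e-6)  # ~ 0.001
#' @export
reynolds <- function(U0, Dh, nu = 8.74e-7) {
  if (any(U0 < 0) || any(Dh < 0) || any(nu <= 0))
    stop("inputs must be non-negative (nu strictly positive)")
  if (any(U0 > 10))
    warning("U0 > 10 m/s: micrometre value passed as metres per second?")
  if (any(Dh > 0.1))
    warning("Dh > 0.1 m: micrometre value passed as metres?")
  U0 * Dh / nu
}

#' Scalar hydraulic state of a conduit system
#'
#' Completes whichever of Q, S, U0, Dh, Re are derivable from the supplied
#' subset (U0 = Q/S, Re = U0 Dh / nu).
#'
#' @param Q m^3/s; \code{S} m^2; \code{U0} m/s; \code{Dh} m; \code{nu}
#'   m^2/s (default 8.74e-7).
#' @param S,U0,Dh see above; any may be NA.
#' @param nu kinematic viscosity (m^2/s).
#' @return a [FlowConditions-class].
#' @export
flowConditions <- function(Q = NA_real_, S = NA_real_, U0 = NA_real_,
                           Dh = NA_real_, nu = 8.74e-7) {
  if (is.na(U0) && !is.na(Q) && !is.na(S)) U0 <- meanVelocity(Q, S)
  if (is.na(Q) && !is.na(U0) && !is.na(S)) Q <- U0 * S
  Re <- if (!is.na(U0) && !is.na(Dh)) reynolds(U0, Dh, nu) else NA_real_
  new("FlowConditions", Q = Q, S = S, U0 = U0, nu = nu, Dh = Dh, Re = Re)
}

#' Match a chip operating point to a target Reynolds number
#'
#' Inverts Re = U Dh / nu for the chip: the mean chip velocity that puts the
#' microchannel at the same Reynolds number as the plant vessels, the total
#' volumetric flow it implies, and its split over the two Y-junction inlets
#' at inlet ratio R = Q2/Q1 (Q1 + Q2 = Q).
#'
#' @param targetRe Reynolds number to match (>= 0).
#' @param chip a [DuctGeometry-class] (default the 120 x 240 um outlet).
#' @param nu kinematic viscosity (m^2/s).
#' @param ratioR inlet flow ratio Q2/Q1 in (0, 1].
#' @return list: \code{U_chip_m_s}, \code{Q_m3_s}, \code{Q1_m3_s},
#'   \code{Q2_m3_s} and the same flows in mL/h (\code{Q_mL_h}, ...).
#' @examples
#' matchChipOperatingPoint(0.012)$U_chip_m_s  # ~ 6.56e-5
#' @export
matchChipOperatingPoint <- function(targetRe, chip = ductGeometry(),
                                    nu = 8.74e-7, ratioR = 1) {
  if (targetRe < 0) stop("targetRe must be non-negative")
  if (ratioR <= 0 || ratioR > 1) stop("ratioR must lie in (0, 1]")
  if (chip@width <= 0 || chip@height <= 0) stop("degenerate chip geometry")
  U <- targetRe * nu / chip@hydraulicDiameter
  Q <- U * chip@width * chip@height
  Q1 <- Q / (1 + ratioR)
  Q2 <- Q - Q1  # exact conservation: Q1 + Q2 = Q to the last bit
  list(U_chip_m_s = U, Q_m3_s = Q, Q1_m3_s = Q1, Q2_m3_s = Q2,
       Q_mL_h = m3sToMlh(Q), Q1_mL_h = m3sToMlh(Q1), Q2_mL_h = m3sToMlh(Q2))
}

#' Analytic laminar profile of a rectangular duct
#'
#' Evaluates the classical Fourier-series solution for fully developed
#' pressure-driven laminar flow in a rectangular duct of width w (y) and
#' height h (z), normalized so that the cross-section mean equals U0. This
#' is the oracle against which PIV profile recovery is checked, and the
#' source of the "centerline maximum close to 2 U0" property of the 1:2
#' chip outlet.
#'
#' @param geometry a [DuctGeometry-class].
#' @param U0 target cross-section mean velocity (any unit; the profile
#'   scales linearly).
#' @param truncationN number of series terms (odd terms used; >= 25
#'   required; default 101). An error is raised if the tail estimate
#'   suggests worse than 0.1\% convergence.
#' @param gridN evaluation grid per axis (default 201).
#' @return list: \code{y, z} (m), \code{u} matrix \code{[z, y]},
#'   \code{maxMeanRatio} (centerline maximum / cross-section mean).
#' @examples
#' rectDuctProfile(ductGeometry(120, 120))$maxMeanRatio  # ~ 2.096
#' @export
rectDuctProfile <- function(geometry, U0 = 1, truncationN = 101,
                            gridN = 201) {
  stopifnot(is(geometry, "DuctGeometry"))
  if (truncationN < 25) stop("truncationN must be >= 25")
  # orient the series along the shorter side for fastest convergence
  a <- min(geometry@width, geometry@height) / 2
  b <- max(geometry@width, geometry@height) / 2
  y <- seq(-a, a, length.out = gridN)
  z <- seq(-b, b, length.out = gridN)
  u <- matrix(0, gridN, gridN)  # [z, y]
  terms <- seq(1, truncationN, by = 2)
  for (n in terms) {
    k <- n * pi / (2 * a)
    # cosh(k z)/cosh(k b) in overflow-safe exponential form
    ratio <- (exp(k * (z - b)) + exp(-k * (z + b))) / (1 + exp(-2 * k * b))
    u <- u + (-1)^((n - 1) / 2) / n^3 * outer(1 - ratio, cos(k * y))
  }
  lastN <- terms[length(terms)]
  if (1 / lastN^3 > 1e-3 * max(u))
    stop("series truncation too small for 0.1% convergence")
  wts <- rep(1, gridN); wts[c(1, gridN)] <- 0.5
  meanU <- sum(outer(wts, wts) * u) / (gridN - 1)^2
  u <- u * (U0 / meanU)
  list(y = y, z = z, u = u, maxMeanRatio = max(u) / U0)
}
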