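#' Generate a synthetic tracer-particle image pair
#'
#' Renders two 8-bit frames of Gaussian tracer particles in which every
#' frame-B particle is the corresponding frame-A particle displaced by the
#' prescribed field evaluated at its frame-A position (first-order scheme,
#' adequate for the small-displacement regime the engine targets). Particles
#' are seeded uniformly over a domain padded by the maximum displacement, so
#' tracers leaving the frame are implicitly dropped and fresh ones enter at
#' the inflow edge: the imaged particle density is stationary between frames.
#' Particles render as pixel-integrated Gaussians (erf differences), the
#' image model of diffraction-limited 2 um tracers at ~1 um/px.
#'
#' @param field a [DisplacementField-class]; must be finite and bounded by
#'   \code{maxDisplacement} on the padded domain.
#' @param width,height frame size in px.
#' @param density particle density in particles/px^2 (default 0.02, about
#'   5-10 tracers per final 32x8 interrogation window).
#' @param diameter particle image diameter in px at the e^-2 intensity level
#'   (default 3); the Gaussian sd is diameter/4.
#' @param intensity peak pixel value of a pixel-centered particle
#'   (default 200 on the 8-bit scale).
#' @param noiseSd additive Gaussian noise standard deviation in counts
#'   (default 2).
#' @param seed integer seed; identical (seed, params) reproduce the pair
#'   bit-exactly.
#' @param maxDisplacement stated bound on |field| in px (default 10);
#'   exceeding it is an error, as truth would leak out of the padded domain.
#' @return a [ParticleImagePair-class].
#' @examples
#' p <- makeParticleImagePair(uniformField(3, 0, 96, 48), 96, 48, seed = 1)
#' p
#' @export
makeParticleImagePair <- function(field, width = NULL, height = NULL,
                                  density = 0.02, diameter = 3,
                                  intensity = 200, noiseSd = 2, seed = 1,
                                  maxDisplacement = 10) {
  stopifnot(is(field, "DisplacementField"))
  if (is.null(width)) width <- field@width
  if (is.null(height)) height <- field@height
  if (density <= 0) stop("density must be positive")
  if (diameter < 2) stop("diameter must be >= 2 px")
  pad <- ceiling(maxDisplacement) + ceiling(diameter)
  nPart <- round(density * (width + 2 * pad) * (height + 2 * pad))
  if (nPart < 1) stop("density yields zero particles for this frame size")
  sigma <- diameter / 4

  withSeed(seed, {
    px <- stats::runif(nPart, -pad, width + pad)
    py <- stats::runif(nPart, -pad, height + pad)
    amp <- intensity * stats::runif(nPart, 0.8, 1)
    d <- evalField(field, px, py)
    if (any(abs(d) > maxDisplacement))
      stop("field exceeds maxDisplacement on the padded domain")
    a <- cpp_render_particles(height, width, px, py, amp, sigma)
    b <- cpp_render_particles(height, width, px + d[, "dx"], py + d[, "dy"],
                              amp, sigma)
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    if (noiseSd > 0) {
      a <- a + matrix(stats::rnorm(length(a), 0, noiseSd), nrow(a))
      b <- b + matrix(stats::rnorm(length(b), 0, noiseSd), nrow(b))
    }
    new("ParticleImagePair",
        frameA = quantize8(a), frameB = quantize8(b), truth = field,
        params = list(density = density, diameter = diameter,
                      intensity = intensity, noiseSd = noiseSd,
                      maxDisplacement = maxDisplacement),
        seed = as.integer(seed))
  })
}

#' Generate an ensemble of seeded particle-image pairs
#'
#' @param field,... passed to [makeParticleImagePair()].
#' @param n number of pairs.
#' @param seed base seed; pair k uses seed + k - 1.
#' @return list of [ParticleImagePair-class].
#' @export
makeParticlePairEnsemble <- function(field, n, seed = 1, ...) {
  lapply(seq_len(n) - 1L,
         function(k) makeParticleImagePair(field, seed = seed + k, ...))
}
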