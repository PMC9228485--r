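# Shared fixtures: small, fast synthetic inputs built in code.

# A standard uniform-displacement tracer pair on a frame that fits one
# 32 x 128 initial window plus refinement margin.
uniformPair <- function(dx, dy = 0, seed = 1, ...) {
  makeParticleImagePair(uniformField(dx, dy, 192, 64), seed = seed, ...)
}

# A noiseless velocity field with constant (u0, v0) on an ny x nx grid,
# for validation-rule tests where PIV itself is not under test.
constantField <- function(u0, v0 = 0, ny = 9, nx = 9, snr = 5) {
  new("VelocityField", x = seq(16, by = 16, length.out = nx),
      y = seq(4, by = 4, length.out = ny),
      u = matrix(u0, ny, nx), v = matrix(v0, ny, nx),
      snr = matrix(snr, ny, nx), valid = matrix(TRUE, ny, nx),
      replaced = matrix(FALSE, ny, nx), passIndex = 1L,
      calibration = 1, dt = 1)
}

smallRingSpec <- function() {
  data.frame(radius = c(60, 120), count = c(5, 8),
             aMin = c(8, 10), aMax = c(14, 18), ratioMin = c(0.6, 0.6))
}
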