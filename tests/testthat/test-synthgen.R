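# Synthetic generators: determinism, displacement contracts, flux properties.

test_that("particle pair generation honors displacement and determinism contracts", {
  # zero displacement, no noise: identical frames
  p0 <- makeParticleImagePair(uniformField(0, 0, 96, 48), noiseSd = 0, seed = 3)
  expect_identical(frameA(p0), frameB(p0))

  # integer translation, no noise: frame B is frame A shifted by 3 px in x
  # (interior region, away from the replenished inflow edge)
  p3 <- makeParticleImagePair(uniformField(3, 0, 96, 48), noiseSd = 0, seed = 3)
  a <- frameA(p3)[, 10:80]
  b <- frameB(p3)[, 13:83]
  expect_equal(a, b)

  # same seed and params twice: bit-identical
  q1 <- uniformPair(1.7, 0.3, seed = 9)
  q2 <- uniformPair(1.7, 0.3, seed = 9)
  expect_identical(frameA(q1), frameA(q2))
  expect_identical(frameB(q1), frameB(q2))
  # different seed: different images
  q3 <- uniformPair(1.7, 0.3, seed = 10)
  expect_false(identical(frameA(q1), frameA(q3)))
})

test_that("particle density is stationary between frames for bounded fields", {
  p <- makeParticleImagePair(uniformField(6, 2, 192, 64), seed = 2)
  # total rendered intensity is an areal particle-count proxy
  ia <- sum(as.numeric(frameA(p)))
  ib <- sum(as.numeric(frameB(p)))
  expect_lt(abs(ia - ib) / ia, 0.05)
})

test_that("generator rejects invalid parameters", {
  f <- uniformField(1, 0, 96, 48)
  expect_error(makeParticleImagePair(f, density = 0), "density")
  expect_error(makeParticleImagePair(f, diameter = 1), "diameter")
  expect_error(makeParticleImagePair(f, noiseSd = -1), "noiseSd")
  expect_error(
    makeParticleImagePair(uniformField(30, 0, 96, 48), maxDisplacement = 10),
    "maxDisplacement")
})

test_that("y-merge field conserves flux, is symmetric at R=1 and wall-shifted at R=0.25", {
  fs <- yMergeField(1, 4, 1200, 64)
  flux <- vapply(c(50, 300, 700, 1100), function(s) fieldFlux(fs, s), 0)
  expect_lt(max(abs(flux - flux[1])) / flux[1], 0.01)
  expect_equal(flux[1], 4 * 64, tolerance = 1e-4)

  # symmetry about the centerline at every station for R = 1
  y <- seq(0, 64, by = 0.5)
  for (s in c(10, 200, 900)) {
    u <- evalField(fs, rep(s, length(y)), y)[, "dx"]
    expect_equal(u, rev(u), tolerance = 1e-12)
  }

  # R = 0.25: near-inlet transverse peak offset toward the high-flux side
  fa <- yMergeField(0.25, 4, 1200, 64)
  u <- evalField(fa, rep(10, length(y)), y)[, "dx"]
  expect_lt(y[which.max(u)], 32)
  # far downstream the profile relaxes to the symmetric duct parabola
  uFar <- evalField(fa, rep(1195, length(y)), y)[, "dx"]
  expect_equal(uFar, rev(uFar), tolerance = 0.05 * max(uFar))
  expect_error(yMergeField(0, 4, 100, 64), "ratioR")
  expect_error(yMergeField(1.5, 4, 100, 64), "ratioR")
})

test_that("y-merge transverse component is continuity-consistent and wall-bounded", {
  f <- yMergeField(0.25, 4, 1200, 64)
  d <- evalField(f, c(10, 10, 500), c(0, 64, 0))
  expect_equal(unname(d[, "dy"]), c(0, 0, 0), tolerance = 1e-10)
})

test_that("vessel phantom matches its truth table and is seed-deterministic", {
  ph1 <- makeVesselPhantom(smallRingSpec(), imageSize = 340, seed = 5)
  ph2 <- makeVesselPhantom(smallRingSpec(), imageSize = 340, seed = 5)
  expect_identical(labelImage(ph1), labelImage(ph2))
  tr <- truthTable(ph1)
  labs <- sort(unique(as.vector(labelImage(ph1))))
  expect_identical(as.integer(labs[labs != 0]), seq_len(nrow(tr)))
  # every truth row corresponds to exactly one connected region
  for (id in tr$label) {
    m <- EBImage::bwlabel(labelImage(ph1) == id)
    expect_equal(max(m), 1)
  }
})

test_that("a circular vessel yields equal truth semi-axes", {
  spec1 <- data.frame(radius = 0, count = 1, aMin = 20, aMax = 20,
                      ratioMin = 1)
  ph <- makeVesselPhantom(spec1, imageSize = 120, seed = 1)
  tr <- truthTable(ph)
  expect_equal(tr$a_px, 20)
  expect_equal(tr$b_px, 20)
})

test_that("MRI phantom has the documented layout and noiseless truth curves", {
  ser <- makeMriPhantom(seed = 4)
  expect_identical(dim(seriesData(ser)), c(18L, 19L, 32L, 32L))

  ser0 <- makeMriPhantom(nSlices = 4, nTimes = 6, nodeSlices = c(1, 3),
                         height = 16, width = 16, noiseSd = 0, seed = 1)
  rm0 <- regionMeans(ser0)
  tmin <- (0:5) * ser0@timeStep
  truthNode <- 100 + 50 * (1 - exp(-tmin / 100))
  expect_equal(unname(rm0$stem[1, ]), truthNode, tolerance = 1e-12)
  expect_equal(unname(rm0$stem[2, ]), rep(100, 6), tolerance = 1e-12)
  expect_equal(unname(rm0$air[1, ]), rep(25, 6), tolerance = 1e-12)

  # amplitude 0 everywhere: flow matrix is 0 within noise
  serNull <- makeMriPhantom(nSlices = 4, nTimes = 6, nodeSlices = c(1, 3),
                            height = 16, width = 16, amplitude = 0,
                            noiseSd = 1, seed = 2)
  expect_lt(max(abs(flowMatrix(flowSignal(serNull)))), 0.1)

  # determinism
  s1 <- makeMriPhantom(nSlices = 3, nTimes = 4, nodeSlices = 1,
                       height = 12, width = 12, seed = 7)
  s2 <- makeMriPhantom(nSlices = 3, nTimes = 4, nodeSlices = 1,
                       height = 12, width = 12, seed = 7)
  expect_identical(seriesData(s1), seriesData(s2))
  expect_error(makeMriPhantom(nSlices = 1), "slices")
  expect_error(makeMriPhantom(nSlices = 4, nodeSlices = 1:4), "internode")
})

test_that("seed fan-out is deterministic, stage-sensitive and 32-bit safe", {
  expect_identical(deriveSeed(7, "piv"), deriveSeed(7, "piv"))
  expect_false(deriveSeed(7, "piv") == deriveSeed(7, "mri"))
  expect_false(deriveSeed(7, "piv") == deriveSeed(8, "piv"))
  expect_lt(deriveSeed(.Machine$integer.max, "synth-vessels"), 2^31)
})
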