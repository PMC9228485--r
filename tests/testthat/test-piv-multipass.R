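# Multipass engine, validation stages, ensemble averaging, profiles.

test_that("zero-displacement pair gives a null field", {
  p <- makeParticleImagePair(uniformField(0, 0, 192, 64), seed = 21)
  f <- multipassPiv(p)
  v <- velocities(f); ok <- validFlags(f)
  expect_lt(max(abs(v$u[ok])), 0.05)
  expect_lt(max(abs(v$v[ok])), 0.05)
})

test_that("noise-free integer shifts are recovered exactly by the correlation peak", {
  set.seed(31)
  big <- matrix(round(runif(64 * 256) * 255), 64, 256)
  wA <- big[17:48, 51:178]   # 32 x 128
  wB <- big[17:48, 48:175]   # pattern displaced +3 px in x
  pl <- correlateWindow(wA, wB)
  expect_identical(pl@peakLag, c(0L, 3L))
  # zero-padded linear correlation: the peak is slightly below 1 because
  # the 3-px non-overlap carries no signal, but the lag itself is exact
  expect_gt(pl@peakValue, 0.9)
})

test_that("translation equivariance: shifting both frames leaves the field unchanged", {
  p <- uniformPair(2.4, 0.6, seed = 41)
  a <- frameA(p); b <- frameB(p)
  # common integer shift of both frames (crop the same interior)
  a2 <- a[5:60, 9:184]; b2 <- b[5:60, 9:184]
  cfg <- pivConfig(initialWindow = c(16, 64), finalWindow = c(8, 32),
                   nPasses = 2)
  f1 <- multipassPiv(p, cfg)
  p2 <- new("ParticleImagePair", frameA = a2, frameB = b2, truth = p@truth,
            params = p@params, seed = p@seed)
  f2 <- multipassPiv(p2, cfg)
  m1 <- mean(velocities(f1)$u[validFlags(f1)])
  m2 <- mean(velocities(f2)$u[validFlags(f2)])
  expect_equal(m1, m2, tolerance = 0.02)
})

test_that("mean-flow accuracy holds at the 8 px and 2 px operating points", {
  # reduced ensembles here; the full-ensemble figures live in the
  # acceptance suite
  for (d in c(8, 2)) {
    means <- vapply(1:5, function(s) {
      f <- multipassPiv(uniformPair(d, seed = 500 + s))
      mean(velocities(f)$u[validFlags(f)])
    }, 0)
    relErr <- abs(mean(means) - d) / d
    expect_lt(relErr, if (d == 8) 0.01 else 0.04)
  }
})

test_that("SNR validation flags below-threshold nodes and is idempotent", {
  f <- constantField(2)
  f@snr[3, 4] <- 1.5
  f@snr[5, 5] <- 2.5
  v1 <- validateSnr(f, 2)
  expect_false(validFlags(v1)[3, 4])
  expect_true(validFlags(v1)[5, 5])
  # all nodes above threshold: unchanged
  g <- constantField(2)
  expect_identical(validFlags(validateSnr(g, 2)), validFlags(g))
  # twice equals once
  v2 <- validateSnr(v1, 2)
  expect_identical(validFlags(v2), validFlags(v1))
})

test_that("normalized median test flags and replaces outliers", {
  # spatially uniform field: unchanged
  f <- constantField(3, 1)
  g <- validateAdaptiveMedian(f)
  expect_identical(g@u, f@u)
  expect_true(all(validFlags(g)))

  # single 10x outlier: flagged and replaced by the neighbor median
  f1 <- constantField(3)
  f1@u[5, 5] <- 30
  g1 <- validateAdaptiveMedian(f1)
  expect_false(validFlags(g1)[5, 5])
  expect_true(g1@replaced[5, 5])
  expect_equal(g1@u[5, 5], 3)

  # two adjacent outliers within the 7x7 region: both flagged
  f2 <- constantField(3)
  f2@u[5, 5] <- 30
  f2@u[5, 6] <- 28
  g2 <- validateAdaptiveMedian(f2)
  expect_false(validFlags(g2)[5, 5])
  expect_false(validFlags(g2)[5, 6])
  expect_equal(g2@u[5, 5], 3)
  expect_equal(g2@u[5, 6], 3)

  expect_error(validateAdaptiveMedian(constantField(1, ny = 3, nx = 3),
                                      region = c(7, 7)), "larger")
  expect_error(validateAdaptiveMedian(constantField(1), region = c(6, 7)),
               "odd")
})

test_that("two-stage validation is order-stable (applying twice equals once)", {
  f <- constantField(3)
  f@u[4, 4] <- -20
  f@snr[2, 7] <- 1.2
  once <- validateAdaptiveMedian(validateSnr(f, 2))
  twice <- validateAdaptiveMedian(validateSnr(once, 2))
  expect_identical(once@u, twice@u)
  expect_identical(once@v, twice@v)
  expect_identical(validFlags(once), validFlags(twice))
})

test_that("ensemble averaging is idempotent and respects the validity quorum", {
  f <- constantField(2, 1)
  avg <- ensembleAverage(list(f, f, f))
  expect_equal(avg@u, f@u)
  expect_equal(avg@v, f@v)
  expect_true(all(validFlags(avg)))

  # a node valid in fewer than half the inputs is invalid in the mean
  f2 <- constantField(2, 1)
  f2@valid[1, 1] <- FALSE
  f3 <- constantField(2, 1)
  f3@valid[1, 1] <- FALSE
  avg2 <- ensembleAverage(list(f, f2, f3))
  expect_false(validFlags(avg2)[1, 1])
  expect_true(validFlags(avg2)[2, 2])

  g <- constantField(2, 1, ny = 5, nx = 5)
  expect_error(ensembleAverage(list(f, g)), "grid")
  expect_error(ensembleAverage(list()), "at least one")
})

test_that("ensemble-mean error shrinks like 1/sqrt(N)", {
  # Monte-Carlo scaling on constructed noisy fields (sd 0.5 px per node)
  set.seed(77)
  rmsAt <- function(N) {
    flds <- lapply(seq_len(N), function(i) {
      f <- constantField(2)
      f@u <- f@u + matrix(rnorm(81, 0, 0.5), 9, 9)
      f
    })
    avg <- ensembleAverage(flds)
    sqrt(mean((avg@u - 2)^2))
  }
  r <- vapply(c(10, 40, 160), rmsAt, 0)
  # each 4x ensemble growth should halve the RMS error (within MC slack)
  expect_lt(r[2] / r[1], 0.75)
  expect_lt(r[3] / r[2], 0.75)
  fit <- lm(log(r) ~ log(c(10, 40, 160)))
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.2)
})

test_that("profiles are symmetric for Poiseuille input and conserve station flux", {
  fld <- poiseuilleField(6, 192, 64)
  pairs <- makeParticlePairEnsemble(fld, 6, seed = 70)
  avg <- ensembleAverage(lapply(pairs, multipassPiv))
  prof <- extractProfile(avg, stationX = 96, U0 = 6)
  # maximum at the centerline, symmetric within measurement noise
  expect_equal(prof$y_um[which.max(prof$u_um_s)], 32, tolerance = 8)
  expect_equal(prof$u_um_s, rev(prof$u_um_s), tolerance = 0.1 * max(prof$u_um_s))

  # profile integral approximates the generator station flux
  h <- diff(prof$y_um[1:2])
  measured <- sum((prof$u_um_s[-1] + prof$u_um_s[-nrow(prof)]) / 2) * h
  # truth flux over the same y extent
  y <- seq(min(prof$y_um), max(prof$y_um), length.out = 201)
  u <- evalField(fld, rep(96, 201), y)[, "dx"]
  truth <- sum((u[-1] + u[-201]) / 2) * diff(y[1:2])
  expect_equal(measured, truth, tolerance = 0.05)

  expect_error(extractProfile(avg, stationX = 1e5), "outside")
})

test_that("stations used for merge-profile reporting are inside default fields", {
  # 160/640/800 um stations on a 1 um/px field of 1000 px length
  fld <- yMergeField(0.5, 4, 1000, 64)
  p <- makeParticleImagePair(fld, width = 1000, height = 64, seed = 9)
  cfg <- pivConfig(nPasses = 2)
  f <- multipassPiv(p, cfg)
  for (s in c(160, 640, 800)) {
    prof <- extractProfile(f, stationX = s, U0 = 4)
    expect_true(nrow(prof) > 5)
    expect_true(all(is.finite(prof$U_over_U0)))
  }
})

test_that("severely underseeded images raise a seeding failure", {
  f <- uniformField(1, 0, 192, 64)
  p <- makeParticleImagePair(f, density = 0.0002, seed = 2)
  expect_error(multipassPiv(p), "seeding|invalid")
})

test_that("calibration converts px/frame to um/s", {
  f <- constantField(2, 1)
  f@calibration <- 1.5   # um/px
  f@dt <- 0.5            # s
  cal <- calibratedVelocities(f)
  expect_equal(cal$u[1, 1], 2 * 1.5 / 0.5)
  expect_equal(cal$v[1, 1], 1 * 1.5 / 0.5)
})
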