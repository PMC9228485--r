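# Label-image morphometry: areas, Crofton perimeter, Dh, ellipses, rings, Re.

mkDisk <- function(r, size = 2 * r + 21) {
  m <- matrix(0L, size, size)
  cx <- size / 2
  for (i in seq_len(size)) for (j in seq_len(size))
    if ((i - 0.5 - cx)^2 + (j - 0.5 - cx)^2 <= r^2) m[i, j] <- 1L
  m
}

test_that("area, perimeter and Dh follow the closed forms on simple shapes", {
  # 10x10 px square at 1 um/px: S = 100 um^2, Crofton P = pi/4*(20+20+40/sqrt2)
  sq <- matrix(0L, 20, 20)
  sq[6:15, 6:15] <- 1L
  rec <- measureLabels(sq, pixelSize = 1)
  expect_equal(rec$S_um2, 100)
  # Crofton on a digital square slightly smooths corners relative to 40
  expect_equal(rec$P_um, 40, tolerance = 0.12)

  # rasterized disk radius 50 px: Dh within 2% of 100 px
  d <- measureLabels(mkDisk(50), pixelSize = 1)
  expect_equal(d$Dh_um, 100, tolerance = 0.02)
  expect_equal(d$S_um2, pi * 50^2, tolerance = 0.01)
})

test_that("hydraulic diameter closed forms", {
  expect_equal(hydraulicDiameter(pi * 23^2, 2 * pi * 23), 46)  # circle: 2r
  expect_equal(hydraulicDiameter(120 * 240, 2 * (120 + 240)), 160)
  expect_equal(hydraulicDiameter(120^2, 4 * 120), 120)         # square duct
  expect_error(hydraulicDiameter(0, 10), "positive")
  expect_error(hydraulicDiameter(10, -1), "positive")
})

test_that("moment ellipse fit recovers phantom axes and is rotation-equivariant", {
  ph <- makeVesselPhantom(smallRingSpec(), imageSize = 340, seed = 8)
  rec <- measureLabels(ph)
  tr <- truthTable(ph)
  ps <- pixelSize(ph)
  expect_equal(rec$a_um, tr$a_px * ps, tolerance = 0.02)
  expect_equal(rec$b_um, tr$b_px * ps, tolerance = 0.02)

  # disk: axis ratio 1 within 1%
  d <- measureLabels(mkDisk(30), pixelSize = 1)
  expect_equal(d$a_um / d$b_um, 1, tolerance = 0.01)

  # 90-degree rotation preserves the axes and shifts orientation by pi/2
  ell <- matrix(0L, 80, 80)
  for (i in 1:80) for (j in 1:80)
    if (((j - 40.5) / 25)^2 + ((i - 40.5) / 10)^2 <= 1) ell[i, j] <- 1L
  r1 <- measureLabels(ell, pixelSize = 1)
  r2 <- measureLabels(t(ell), pixelSize = 1)
  expect_equal(r1$a_um, r2$a_um, tolerance = 1e-6)
  expect_equal(r1$b_um, r2$b_um, tolerance = 1e-6)
  dtheta <- abs(r1$theta_rad - r2$theta_rad) %% pi
  expect_equal(min(dtheta, pi - dtheta), pi / 2, tolerance = 0.02)

  tiny <- matrix(0L, 5, 5); tiny[2, 2:4] <- 1L
  expect_error(measureLabels(tiny, pixelSize = 1), "5 px")
})

test_that("phantom areas are recovered within 3% and labels within tolerance", {
  ph <- makeVesselPhantom(seed = 13)
  rec <- measureLabels(ph)
  tr <- truthTable(ph)
  truthArea <- pi * tr$a_px * tr$b_px * pixelSize(ph)^2
  expect_true(all(abs(rec$S_um2 - truthArea) / truthArea < 0.03))
})

test_that("ring assignment is exact on the phantom and translation-invariant", {
  ph <- makeVesselPhantom(seed = 17)
  ps <- pixelSize(ph)
  rec <- assignRings(measureLabels(ph), ringEdges = c(150, 250, 350) * ps)
  expect_identical(rec$ring, truthTable(ph)$ring)

  # translating all centroids leaves rings unchanged (relative coordinates)
  rec2 <- measureLabels(ph)
  rec2$cx_um <- rec2$cx_um + 57
  rec2$cy_um <- rec2$cy_um - 23
  rec2 <- assignRings(rec2, ringEdges = c(150, 250, 350) * ps)
  expect_identical(rec2$ring, rec$ring)

  # quantile mode, all radii tied: deterministic collapse to ring I
  same <- data.frame(cx_um = c(10, -10, 0, 0), cy_um = c(0, 0, 10, -10),
                     S_um2 = 1)
  tied <- assignRings(same, center = c(0, 0))
  expect_true(all(tied$ring == "I"))
  expect_error(assignRings(same[1:3, ]), ">= 4|ringEdges")
})

test_that("per-vessel Reynolds numbers match the xylem span and are monotone in Dh", {
  rec <- data.frame(Dh_um = c(3.8, 46, 0))
  out <- reynoldsPerVessel(rec, U0 = 221.5, nu = 8.74e-7)
  expect_equal(round(out$Re[2], 3), 0.012)
  expect_equal(round(out$Re[1], 3), 0.001)
  expect_equal(out$Re[3], 0)
  expect_true(all(diff(out$Re[order(out$Dh_um)]) >= 0))
  expect_error(reynoldsPerVessel(rec, U0 = -1), "positive")
})

test_that("stem summary totals partition over rings", {
  ph <- makeVesselPhantom(seed = 19)
  res <- vesselMorphometry(ph, ringEdges = c(150, 250, 350) * pixelSize(ph))
  s <- res$summary
  expect_equal(sum(res$records$S_um2), s$totalArea_um2)
  expect_equal(sum(s$perRing$totalArea_um2), s$totalArea_um2)
  expect_equal(sum(s$perRing$n), nrow(res$records))

  one <- measureLabels(mkDisk(12), pixelSize = 1)
  expect_equal(summarizeStem(one)$totalArea_um2, one$S_um2)
})

test_that("isoperimetric bound and scale covariance hold for every measured region", {
  ph <- makeVesselPhantom(seed = 23)
  rec <- measureLabels(ph)
  expect_true(all(rec$Dh_um <= 2 * sqrt(rec$S_um2 / pi) * 1.05))

  # doubling pixel size doubles Dh and quadruples S on the same raster
  rec2 <- measureLabels(labelImage(ph), pixelSize = 2 * pixelSize(ph))
  expect_equal(rec2$S_um2, 4 * rec$S_um2)
  expect_equal(rec2$Dh_um, 2 * rec$Dh_um)
})

test_that("morphometry output is byte-deterministic for identical rasters", {
  ph <- makeVesselPhantom(smallRingSpec(), imageSize = 340, seed = 29)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(measureLabels(ph), f1, row.names = FALSE)
  write.csv(measureLabels(ph), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("degenerate label inputs raise explicit errors", {
  expect_error(measureLabels(matrix(0L, 10, 10)), "no regions")
  expect_error(measureLabels(matrix(0.5, 3, 3)), "integer")
  expect_error(measureLabels(matrix(1L, 4, 4), pixelSize = 0), "pixelSize")
})
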