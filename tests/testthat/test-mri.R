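# MRI flow-signal normalization and slice classification.

test_that("region means are exact on constructed intensities", {
  ser <- makeMriPhantom(nSlices = 2, nTimes = 3, nodeSlices = 1,
                        height = 16, width = 16, noiseSd = 0, seed = 1)
  # constant field: all means equal the constant
  serC <- ser
  serC@data[] <- 42
  rm <- regionMeans(serC)
  expect_true(all(rm$stem == 42))
  expect_true(all(rm$air == 42))

  # checkerboard 0/100 under the air mask (even pixel count): mean 50
  chk <- matrix(c(0, 100), 16, 16)
  serB <- ser
  for (i in 1:2) for (t in 1:3) serB@data[i, t, , ] <- chk
  rmB <- regionMeans(serB)
  airCells <- sum(seriesMasks(ser)[1, , ] == 3)
  if (airCells %% 2 == 0) expect_equal(rmB$air[1, 1], 50)
  expect_equal(rmB$air[1, 1], mean(chk[seriesMasks(ser)[1, , ] == 3]))
})

test_that("flow-signal normalization reproduces the defining arithmetic", {
  # stem 100 -> 110 with air constant at 25: F = (110-100)/25 = 0.4
  stem <- matrix(c(100, 110), 1)
  air <- matrix(c(25, 25), 1)
  Fm <- normalizeFlowSignal(stem, air)
  expect_identical(flowMatrix(Fm)[1, 1], 0)
  expect_equal(flowMatrix(Fm)[1, 2], 0.4)

  # baseline column is exactly zero for every slice
  set.seed(5)
  stem2 <- matrix(runif(40, 90, 140), 4)
  air2 <- matrix(runif(40, 20, 30), 4)
  expect_true(all(flowMatrix(normalizeFlowSignal(stem2, air2))[, 1] == 0))

  expect_error(normalizeFlowSignal(stem, matrix(c(25, 0), 1)), "air")
  expect_error(normalizeFlowSignal(stem, air[, 1, drop = FALSE]), "shape")
})

test_that("constant offsets leave the numerator unchanged (air-only effect)", {
  stem <- matrix(c(100, 108, 116), 1)
  air <- matrix(c(25, 26, 24), 1)
  f0 <- flowMatrix(normalizeFlowSignal(stem, air))
  # offset every frame of the slice by +40: numerator invariant, so the
  # signal changes only through the shifted air normalization
  f1 <- flowMatrix(normalizeFlowSignal(stem + 40, air + 40))
  expect_equal(f1[1, -1] * (air[1, -1] + 40), f0[1, -1] * air[1, -1])
})

test_that("noiseless phantom: internode rows are identically zero, node rows increase", {
  ser <- makeMriPhantom(noiseSd = 0, seed = 2)
  Fm <- flowMatrix(flowSignal(ser))
  node <- ser@truth$class == "node"
  expect_true(all(Fm[!node, ] == 0))
  expect_true(all(apply(Fm[node, ], 1, function(r) all(diff(r) > 0))))
})

test_that("slice classification recovers truth and handles limit cases", {
  ser0 <- makeMriPhantom(noiseSd = 0, seed = 3)
  thr <- defaultSlopeThreshold(ser0)
  cls <- classifySlices(flowSignal(ser0), thr)
  expect_identical(cls$class, ser0@truth$class)

  # all-zero matrix: all internode
  z <- new("FlowSignalMatrix", values = matrix(0, 3, 5),
           slicePositions = 0:2, timeMinutes = (0:4) * 23)
  expect_true(all(classifySlices(z, thr)$class == "internode"))

  # threshold at +Inf: all internode
  clsInf <- classifySlices(flowSignal(ser0), Inf)
  expect_true(all(clsInf$class == "internode"))

  short <- new("FlowSignalMatrix", values = matrix(0, 2, 2),
               slicePositions = 0:1, timeMinutes = c(0, 23))
  expect_error(classifySlices(short, 0), "3 timepoints")
})

test_that("noisy classification stays above 95% accuracy (reduced replicate set)", {
  thr <- defaultSlopeThreshold(makeMriPhantom(noiseSd = 0, seed = 1))
  correct <- 0; total <- 0
  for (s in 1:20) {
    ser <- makeMriPhantom(seed = 1000 + s)
    cls <- classifySlices(flowSignal(ser), thr)
    correct <- correct + sum(cls$class == ser@truth$class)
    total <- total + length(cls$class)
  }
  expect_gte(correct / total, 0.95)
})

test_that("space-time map CSV round-trips the matrix exactly", {
  ser <- makeMriPhantom(nSlices = 4, nTimes = 6, nodeSlices = c(1, 3),
                        height = 16, width = 16, seed = 6)
  Fm <- flowSignal(ser)
  expect_identical(dim(flowMatrix(flowSignal(makeMriPhantom(seed = 7)))),
                   c(18L, 19L))
  csv <- tempfile(fileext = ".csv")
  png <- tempfile(fileext = ".png")
  spacetimeMap(Fm, csvPath = csv, pngPath = png)
  expect_true(file.exists(png))
  back <- readSpacetimeCsv(csv)
  expect_equal(flowMatrix(back), flowMatrix(Fm), tolerance = 1e-12)
  expect_equal(back@timeMinutes, Fm@timeMinutes)

  # malformed header is named in the error
  bad <- tempfile(fileext = ".csv")
  writeLines(c("wrong,t_0_min", "0,0"), bad)
  expect_error(readSpacetimeCsv(bad), "slice_position_mm")
  unlink(c(csv, png, bad))
})
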