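test_that("threshold calibration matches a direct mean + k*SD computation", {
  ctl <- generateControlSample(80, noiseModel(10, 0, 5, 0.05), seed = 14)
  th <- calibrateThresholds(ctl$events, kSigma = 3)
  # independent two-pass mean/SD over the same per-cell values
  tab <- do.call(rbind, lapply(ctl$events, function(e) cellData(segmentCells(e))))
  g <- tab$gd2[!tab$isFragment]
  m <- sum(g) / length(g)
  s <- sqrt(sum((g - m)^2) / (length(g) - 1))
  expect_equal(th@gd2Pos, m + 3 * s, tolerance = 1e-12)
  # the calibrated cut sits above the bulk of the realized control values
  expect_gte(th@gd2Pos, max(g) - 3 * s)

  th4 <- calibrateThresholds(ctl$events, kSigma = 4)
  expect_gte(th4@gd2Pos, th@gd2Pos)
  expect_gte(th4@cd45Pos, th@cd45Pos)
  expect_gte(th4@dapiPos, th@dapiPos)
})

test_that("degenerate zero-variance controls fall back to mean + epsilon", {
  ctl <- generateControlSample(60, zeroNoise(), seed = 5)
  w <- capture_warnings(th <- calibrateThresholds(ctl$events))
  expect_match(w, "degenerate", all = TRUE)
  expect_length(w, 3)  # one per channel on fully noiseless controls
  expect_gt(th@gd2Pos, 0)
  expect_lt(th@gd2Pos, 1)  # background is zero, epsilon is small
})

test_that("noiseless segmentation recovers every rendered cell and its mask", {
  ev <- generateEvent(compositionSpec(nNb = 1, nImmune = 1, nOther = 1),
                      zeroNoise(), seed = 23)
  cs <- segmentCells(ev)
  expect_equal(nCells(cs), 3)
  tr <- eventTruth(ev)
  # match each truth cell to the best-overlapping segmented cell; IoU near 1
  for (i in tr$cells$cellId) {
    tpx <- which(tr$labelMap == i)
    ious <- vapply(cs@cells, function(cl) {
      length(intersect(cl$pixels, tpx)) / length(union(cl$pixels, tpx))
    }, numeric(1))
    expect_gte(max(ious), 0.9)
  }
})

test_that("touching nuclei are split by the watershed", {
  dim <- c(64L, 64L)
  # two discs whose nuclei touch: a single DAPI component with two maxima
  n1 <- discIdx(28, 32, 6, dim); n2 <- discIdx(39, 32, 6, dim)
  ev <- makeManualEvent(dim, bf = union(n1, n2), dapi = union(n1, n2))
  expect_equal(max(EBImage::bwlabel(foregroundMask(ev@channels$DAPI))), 1)
  cs <- segmentCells(ev, eventId = "W1")
  expect_equal(nCells(cs), 2)
})

test_that("DAPI-negative brightfield objects become fragment placeholders", {
  ev <- generateEvent(compositionSpec(nNb = 1, nFragments = 1), zeroNoise(),
                      seed = 31, attachFragments = FALSE)
  cs <- segmentCells(ev)
  tab <- cellData(cs)
  expect_equal(sum(!tab$isFragment), 1)
  expect_equal(sum(tab$isFragment), 1)
})

test_that("marker logic is total over all eight combinations", {
  th <- markerThresholds(gd2Pos = 10, cd45Pos = 10, dapiPos = 10)
  combos <- expand.grid(gd2 = c(0, 20), cd45 = c(0, 20), dapi = c(0, 20))
  want <- function(g, c, d) {
    if (d == 0) return("FRAGMENT")
    if (g > 10 && c <= 10) return("NB")
    if (g <= 10 && c > 10) return("IMMUNE")
    if (g <= 10 && c <= 10) return("OTHER_DN")
    "OTHER_DP"
  }
  for (i in seq_len(nrow(combos))) {
    cell <- as.list(combos[i, ])
    expect_equal(classifyCell(cell, th),
                 want(cell$gd2, cell$cd45, cell$dapi))
  }
  # the documented marker signatures
  expect_equal(classifyCell(list(gd2 = 20, cd45 = 0, dapi = 20), th), "NB")
  expect_equal(classifyCell(list(gd2 = 0, cd45 = 20, dapi = 20), th), "IMMUNE")
  expect_equal(classifyCell(list(gd2 = 20, cd45 = 20, dapi = 20), th), "OTHER_DP")
  expect_equal(classifyCell(list(gd2 = 20, cd45 = 20, dapi = 20), th,
                            reclassifyDoublePositive = TRUE), "NB")
})

test_that("every cell type is recovered exactly on zero-noise events", {
  tpls <- list(compositionSpec(nNb = 1), compositionSpec(nImmune = 1),
               compositionSpec(nNb = 1, nImmune = 1, nOther = 1),
               compositionSpec(nNb = 2, nImmune = 1))
  s <- generateSample(40, tpls, c(0.25, 0.25, 0.25, 0.25), volumeMl = 5,
                      noise = zeroNoise(), seed = 44, canvas = 96)
  ctl <- generateControlSample(80, zeroNoise(), seed = 45, canvas = 96)
  th <- suppressWarnings(calibrateThresholds(ctl$events))
  css <- lapply(s$events, function(e) classifyCells(segmentCells(e), th))
  expect_equal(typingAccuracy(s$events, css), 1)
})
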