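test_that("noiseless events render the requested composition with cells in contact", {
  cases <- list(list(spec = compositionSpec(nNb = 2), nb = 2, other = 0),
                list(spec = compositionSpec(nNb = 1, nImmune = 1), nb = 1, other = 1),
                list(spec = compositionSpec(nNb = 1, nImmune = 5), nb = 1, other = 5))
  for (cs in cases) {
    ev <- generateEvent(cs$spec, zeroNoise(), seed = 5)
    tr <- eventTruth(ev)
    expect_equal(sum(tr$cells$type == "NB"), cs$nb)
    expect_equal(sum(tr$cells$type != "NB"), cs$other)
    # every cell touches at least one other cell (ground-truth contact)
    dim <- dim(channelImage(ev, "BF"))
    n <- nrow(tr$cells)
    if (n >= 2) {
      for (i in seq_len(n)) {
        dmin <- min(vapply(setdiff(seq_len(n), i), function(j)
          ifcClusters:::maskMinDistance(which(tr$labelMap == i),
                                        which(tr$labelMap == j), dim),
          numeric(1)))
        expect_lte(dmin, 2)
      }
    }
  }
})

test_that("noiseless channels are piecewise constant and marker-correct", {
  ev <- generateEvent(compositionSpec(nNb = 1, nImmune = 1), zeroNoise(),
                      seed = 9)
  tr <- eventTruth(ev)
  nbId <- tr$cells$cellId[tr$cells$type == "NB"]
  imId <- tr$cells$cellId[tr$cells$type == "IMMUNE"]
  gd2 <- channelImage(ev, "GD2"); cd45 <- channelImage(ev, "CD45")
  expect_true(all(gd2[tr$labelMap == nbId] > 0))
  expect_true(all(gd2[tr$labelMap == imId] == 0))
  expect_true(all(cd45[tr$labelMap == imId] > 0))
  expect_true(all(cd45[tr$labelMap == nbId] == 0))
  # piecewise constant: only background and amplitude values present
  expect_lte(length(unique(as.numeric(gd2))), 2)
})

test_that("event generation is deterministic and refuses impossible canvases", {
  a <- generateEvent(compositionSpec(nNb = 2, nImmune = 2), noiseModel(), seed = 77)
  b <- generateEvent(compositionSpec(nNb = 2, nImmune = 2), noiseModel(), seed = 77)
  expect_identical(a@channels, b@channels)
  expect_identical(eventTruth(a)$cells, eventTruth(b)$cells)
  expect_error(generateEvent(compositionSpec(nNb = 6), zeroNoise(), seed = 1,
                             canvas = 20),
               "canvas overflow")
})

test_that("sample truth tallies the realized template draws", {
  singles <- list(compositionSpec(nNb = 1))
  s <- generateSample(100, singles, 1, volumeMl = 5, noise = zeroNoise(),
                      seed = 3)
  expect_equal(unname(s$totals), c(100, 0, 0))

  tpls <- list(compositionSpec(nNb = 1), compositionSpec(nNb = 1, nImmune = 1))
  s2 <- generateSample(60, tpls, c(0.5, 0.5), volumeMl = 5,
                       noise = zeroNoise(), seed = 8)
  # derived oracle: tally of the recorded template draws
  expect_equal(unname(s2$totals[["heterotypic"]]), sum(s2$truth$templateIdx == 2))
  expect_equal(unname(s2$totals[["single"]]), sum(s2$truth$templateIdx == 1))
  # truth conservation: per-event counts sum to the totals
  expect_equal(sum(s2$truth$category == "heterotypic"),
               unname(s2$totals[["heterotypic"]]))

  s3 <- generateSample(60, tpls, c(0.5, 0.5), volumeMl = 5,
                       noise = zeroNoise(), seed = 8)
  expect_identical(s2$truth, s3$truth)

  expect_error(generateSample(10, tpls, c(0.6, 0.5), seed = 1), "sum to 1")
  expect_error(generateSample(10, tpls, c(0.5, 0.5), volumeMl = 0, seed = 1),
               "positive")
})

test_that("control samples contain no tumour signal and support calibration", {
  ctl <- generateControlSample(60, zeroNoise(), seed = 4)
  expect_true(all(ctl$truth$nNb == 0))
  gd2max <- max(vapply(ctl$events, function(e) max(channelImage(e, "GD2")),
                       numeric(1)))
  expect_equal(gd2max, 0)  # zero-noise controls: GD2 identically background
  expect_error(generateControlSample(20, zeroNoise(), seed = 1), "at least 50")
})

test_that("noiseless positive cells are separable from negative cells", {
  ev <- generateEvent(compositionSpec(nNb = 1, nImmune = 1, nOther = 1),
                      zeroNoise(), seed = 12)
  tr <- eventTruth(ev)
  gd2 <- channelImage(ev, "GD2")
  perCell <- vapply(tr$cells$cellId, function(i)
    stats::median(gd2[tr$labelMap == i]), numeric(1))
  pos <- perCell[tr$cells$type == "NB"]
  neg <- perCell[tr$cells$type != "NB"]
  expect_true(min(pos) - max(neg) >= 0.9 * defaultAmplitudes()[["GD2"]])
})

test_that("events round-trip through multi-page TIFF with sidecar metadata", {
  ev <- generateEvent(compositionSpec(nNb = 1, nFragments = 1), noiseModel(),
                      seed = 30)
  path <- file.path(withr::local_tempdir(), "ev.tif")
  writeEventTIFF(ev, path)
  expect_true(file.exists(sub("\\.tif$", ".json", path)))
  back <- readEventTIFF(path)
  expect_equal(channelNames(back), c("BF", "GD2", "CD45", "DAPI"))
  expect_equal(pixelSize(back), pixelSize(ev))
  for (ch in channelNames(back))
    expect_equal(channelImage(back, ch), channelImage(ev, ch),
                 tolerance = 1e-3)
})

test_that("ground truth CSV uses 0-based coordinates and the declared schema", {
  ev <- generateEvent(compositionSpec(nNb = 2), zeroNoise(), seed = 2)
  path <- file.path(withr::local_tempdir(), "truth.csv")
  writeEventTruth(list(ev), path)
  tab <- read.csv(path)
  expect_named(tab, c("event_id", "cell_id", "type", "centroid_x", "centroid_y"))
  dim <- dim(channelImage(ev, "BF"))
  expect_true(all(tab$centroid_x >= 0 & tab$centroid_x < dim[2]))
  expect_true(all(tab$centroid_y >= 0 & tab$centroid_y < dim[1]))
})
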