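test_that("contact edges follow the boundary-distance rule", {
  dim <- c(64L, 96L)
  # A-B-C chain: A and B adjacent, B and C adjacent, A and C far apart
  cs <- cellSet("EV", dim, list(
    makeTypedCell(1, "NB", 20, 30, r = 5, dim = dim),
    makeTypedCell(2, "IMMUNE", 31, 30, r = 5, dim = dim),
    makeTypedCell(3, "NB", 42, 30, r = 5, dim = dim)))
  edges <- buildContactGraph(cs, contactDistance = 2)
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$from, edges$to), c("1 2", "2 3"))
  # brute-force oracle: full pairwise pixel distances
  for (k in seq_len(nrow(edges))) {
    a <- cs@cells[[edges$from[k]]]$pixels
    b <- cs@cells[[edges$to[k]]]$pixels
    ra <- ifcClusters:::idxToCoord(a, dim); rb <- ifcClusters:::idxToCoord(b, dim)
    d2 <- outer(ra[, 1], rb[, 1], "-")^2 + outer(ra[, 2], rb[, 2], "-")^2
    expect_equal(edges$dist[k], sqrt(min(d2)))
  }

  far <- cellSet("EV", dim, list(
    makeTypedCell(1, "NB", 20, 30, r = 5, dim = dim),
    makeTypedCell(2, "NB", 45, 30, r = 5, dim = dim)))
  expect_equal(nrow(buildContactGraph(far, contactDistance = 2)), 0)
})

test_that("intactness combines area and solidity as documented", {
  dim <- c(64L, 64L)
  cell <- makeTypedCell(1, "NB", 30, 30, r = 6, dim = dim)
  expect_true(checkIntact(cell))
  expect_gte(cell$solidity, 0.95)  # rendered ellipse is convex

  tiny <- makeTypedCell(2, "FRAGMENT", 10, 10, r = 1, dim = dim)
  expect_false(checkIntact(tiny, minArea = 30))

  # crescent: disc minus an overlapping disc, solidity well below 0.85
  full <- discIdx(30, 30, 10, dim)
  bite <- discIdx(36, 30, 9, dim)
  crescent <- setdiff(full, bite)
  sol <- ifcClusters:::maskSolidity(crescent, dim)
  # convex-hull oracle via an independent point-in-polygon implementation
  rc <- ifcClusters:::idxToCoord(crescent, dim)
  h <- grDevices::chull(rc[, 2], rc[, 1])
  rr <- range(rc[, 1]); cc <- range(rc[, 2])
  g <- expand.grid(row = rr[1]:rr[2], col = cc[1]:cc[2])
  inHull <- pracma::inpolygon(g$col, g$row, rc[h, 2], rc[h, 1],
                              boundary = TRUE)
  expect_equal(sol, length(crescent) / sum(inHull), tolerance = 1e-9)
  expect_lt(sol, 0.85)
  cr <- makeTypedCell(3, "NB", 30, 30, r = 6, dim = dim, solidity = sol)
  expect_false(checkIntact(cr, minSolidity = 0.85))
})

test_that("cluster calls follow the marker-composition rule", {
  run <- function(types) {
    cs <- makeTypedChain(types)
    callClusters(cs, buildContactGraph(cs, 2))
  }
  hom <- run(c("NB", "NB"))
  expect_equal(hom$clusters$label, "HOMOTYPIC")
  expect_equal(hom$clusters$size, 2)

  het <- run(c("NB", "IMMUNE"))
  expect_equal(het$clusters$label, "HETEROTYPIC")
  expect_equal(het$clusters$size, 2)

  none <- run(c("IMMUNE", "IMMUNE"))
  expect_equal(nrow(none$clusters), 0)
  expect_equal(nrow(none$singles), 0)

  mix <- run(c("NB", "NB", "IMMUNE"))
  expect_equal(mix$clusters$label, "HETEROTYPIC")  # purity defines homotypic
  expect_equal(mix$clusters$size, 3)
  expect_equal(mix$clusters$nNb, 2)

  single <- run("NB")
  expect_equal(nrow(single$clusters), 0)
  expect_equal(nrow(single$singles), 1)
})

test_that("fragments attach to clusters without changing size or label", {
  dim <- c(64L, 96L)
  cs <- cellSet("EV", dim, list(
    makeTypedCell(1, "NB", 20, 30, r = 5, dim = dim),
    makeTypedCell(2, "NB", 31, 30, r = 5, dim = dim),
    makeTypedCell(3, "FRAGMENT", 40, 30, r = 2, dim = dim)))
  edges <- buildContactGraph(cs, 2)
  calls <- callClusters(cs, edges)
  expect_equal(calls$clusters$size, 2)
  expect_equal(calls$clusters$label, "HOMOTYPIC")
  expect_equal(calls$clusters$nFragmentsAttached, 1)
})

test_that("cluster membership partitions the intact nucleated cells", {
  set.seed(7)
  for (rep in 1:5) {
    types <- sample(c("NB", "IMMUNE", "OTHER_DN"), sample(3:6, 1),
                    replace = TRUE)
    cs <- makeTypedChain(types, dim = c(64L, 128L))
    calls <- callClusters(cs, buildContactGraph(cs, 2))
    members <- unlist(strsplit(calls$clusters$memberCellIds, ";"))
    expect_equal(anyDuplicated(members), 0)
    expect_equal(sum(calls$clusters$label == "HOMOTYPIC") +
                   sum(calls$clusters$label == "HETEROTYPIC"),
                 nrow(calls$clusters))
    # no cell is both a cluster member and a single-CTC candidate
    expect_length(intersect(members, as.character(calls$singles$cellId)), 0)
  }
})

test_that("non-intact cells cannot join clusters", {
  dim <- c(64L, 96L)
  cells <- list(makeTypedCell(1, "NB", 20, 30, r = 5, dim = dim),
                makeTypedCell(2, "IMMUNE", 31, 30, r = 5, dim = dim,
                              solidity = 0.5))
  cs <- cellSet("EV", dim, cells)
  calls <- callClusters(cs, buildContactGraph(cs, 2))
  expect_equal(nrow(calls$clusters), 0)   # partner fails brightfield QC
  expect_equal(nrow(calls$singles), 1)    # the NB cell is now isolated
})

test_that("size distributions are per-label percentages that sum to 100", {
  calls <- data.frame(label = c("HETEROTYPIC", "HETEROTYPIC", "HETEROTYPIC"),
                      size = c(2, 2, 3))
  h <- sizeDistribution(calls)
  expect_equal(h$n, c(2, 1))
  expect_equal(roundHalfUp(h$pct, 1), c(66.7, 33.3))
  expect_equal(sum(h$pct), 100, tolerance = 1e-9)
  expect_equal(nrow(sizeDistribution(calls[0, ])), 0)
})

test_that("cluster calls serialise with the declared CSV schema", {
  cs <- makeTypedChain(c("NB", "IMMUNE"))
  calls <- callClusters(cs, buildContactGraph(cs, 2))
  path <- file.path(withr::local_tempdir(), "calls.csv")
  writeClusterCalls(calls$clusters, path)
  tab <- read.csv(path)
  expect_named(tab, c("event_id", "size", "n_nb", "n_immune", "n_other",
                      "label", "qc_pass", "n_fragments_attached"))
  expect_equal(tab$size, 2)
})
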