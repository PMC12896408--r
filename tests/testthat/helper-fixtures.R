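# Shared fixture builders: hand-made events and typed cell sets, so tests
# can probe single stages without running the generator.

# disc of radius r centred at (cx, cy), as linear indices
discIdx <- function(cx, cy, r, dim) {
  ifcClusters:::renderEllipse(cx, cy, r, r, dim)
}

# event image built from explicit per-channel masks (zero background)
makeManualEvent <- function(dim = c(64L, 64L), bf = integer(), dapi = integer(),
                            gd2 = integer(), cd45 = integer(), amp = 150) {
  mk <- function(idx) {
    m <- matrix(0, dim[1], dim[2])
    m[idx] <- amp
    m
  }
  eventImage(list(BF = mk(bf), GD2 = mk(gd2), CD45 = mk(cd45),
                  DAPI = mk(dapi)))
}

# a typed synthetic cell for cluster-calling tests; marker intensities are
# consistent with the requested type
makeTypedCell <- function(id, type, cx, cy, r = 5, dim = c(64L, 64L),
                          area = NULL, solidity = NULL) {
  px <- discIdx(cx, cy, r, dim)
  nuc <- if (type == "FRAGMENT") integer() else discIdx(cx, cy, r * 0.6, dim)
  pos <- 150; neg <- 0
  list(cellId = id, pixels = px, nucleusPixels = nuc,
       isFragment = type == "FRAGMENT",
       gd2 = if (type %in% c("NB", "OTHER_DP")) pos else neg,
       cd45 = if (type %in% c("IMMUNE", "OTHER_DP")) pos else neg,
       dapi = if (type == "FRAGMENT") neg else pos,
       area = if (is.null(area)) length(px) else area,
       solidity = if (is.null(solidity)) ifcClusters:::maskSolidity(px, dim)
                  else solidity,
       cellType = type)
}

# a CellSet of typed cells laid out in a horizontal chain, each touching its
# neighbour, all marked intact-sized
makeTypedChain <- function(types, dim = c(64L, 96L), r = 5, gapCenters = 2 * r + 1) {
  cells <- lapply(seq_along(types), function(i)
    makeTypedCell(i, types[i], cx = 10 + (i - 1) * gapCenters, cy = 30,
                  r = r, dim = dim))
  cellSet("EV", dim, cells)
}

# complete contact graph over the given cell ids
completeEdges <- function(ids) {
  if (length(ids) < 2) return(data.frame(from = integer(), to = integer(),
                                         dist = numeric()))
  cmb <- utils::combn(ids, 2)
  data.frame(from = cmb[1, ], to = cmb[2, ], dist = 1)
}

# brute-force transcription of the cluster selection sentence: at least one
# NB cell in contact with at least one additional nucleated cell; homotypic
# iff every member is a tumour cell
bruteClusterRule <- function(nNb, nImmune, nOther) {
  size <- nNb + nImmune + nOther
  isCluster <- size >= 2 && nNb >= 1
  label <- if (!isCluster) NA_character_
           else if (nImmune + nOther == 0) "HOMOTYPIC" else "HETEROTYPIC"
  list(isCluster = isCluster, label = label, size = size)
}

# study-condition noise ladder used for typing-accuracy monotonicity
noiseLadder <- function() list(zeroNoise(),
                               noiseModel(10, 0, 10, 0),
                               noiseModel(10, 0, 35, 0))

zeroNoiseList <- list(background = 0, shot = 0, gaussian = 0, cv = 0)

# enumeration oracle for the Spearman permutation p-value: base cor() per
# permutation, sharing no code with the vectorised implementation
enumSpearmanP <- function(x, y) {
  perms <- ifcClusters:::permutationsMatrix(length(y))
  obs <- abs(stats::cor(x, y, method = "spearman"))
  hits <- vapply(seq_len(nrow(perms)), function(i)
    abs(stats::cor(x, y[perms[i, ]], method = "spearman")) >= obs - 1e-12,
    logical(1))
  mean(hits)
}
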