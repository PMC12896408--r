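# Contact-based cluster calling on typed cells.
#
# A cluster is at least one neuroblastoma cell in contact with at least one
# additional nucleated (DAPI+) cell; clusters made purely of tumour cells
# are homotypic, any non-tumour member makes the cluster heterotypic.
# Fragments never join the contact graph but are recorded when attached.

#' Build the contact graph of an event's objects
#'
#' Undirected edges between every pair of objects (cells and fragments)
#' whose mask boundaries lie within `contactDistance` pixels of each other
#' (minimum pixel-centre distance; adjacent pixels are 1 apart).  No
#' self-edges; each pair appears once.
#'
#' @param cellset a [CellSet-class]
#' @param contactDistance pixels
#' @return data.frame `from, to, dist` of cell ids
#' @export
buildContactGraph <- function(cellset, contactDistance = 2) {
  cells <- cellset@cells
  n <- length(cells)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- maskMinDistance(cells[[i]]$pixels, cells[[j]]$pixels,
                           cellset@imageDim)
      if (d <= contactDistance)
        out[[length(out) + 1L]] <- data.frame(from = cells[[i]]$cellId,
                                              to = cells[[j]]$cellId,
                                              dist = d)
    }
  }
  if (!length(out))
    return(data.frame(from = integer(), to = integer(), dist = numeric()))
  do.call(rbind, out)
}

#' Intact-cell check
#'
#' Automated proxy for visual brightfield inspection of cellular
#' morphology: a cell passes when its mask area reaches `minArea` and its
#' solidity (area over convex-hull area) reaches `minSolidity`, rejecting
#' debris-sized and strongly concave objects.
#'
#' @param cell list with `area` and `solidity` (e.g. an element of a
#'   [CellSet-class]), or a [CellSet-class] for a vectorised check
#' @param minArea px^2
#' @param minSolidity in (0, 1]
#' @return logical (vector for a `CellSet`)
#' @export
checkIntact <- function(cell, minArea = 30, minSolidity = 0.85) {
  if (is(cell, "CellSet"))
    return(vapply(cell@cells, checkIntact, logical(1),
                  minArea = minArea, minSolidity = minSolidity))
  cell$area >= minArea && cell$solidity >= minSolidity
}

#' Call clusters from typed cells and their contact graph
#'
#' Connected components of the contact graph restricted to intact
#' DAPI-positive cells.  A component is a cluster when it has at least two
#' members and contains at least one NB cell; it is `HOMOTYPIC` when every
#' member is an NB cell and `HETEROTYPIC` otherwise.  Components without an
#' NB cell are discarded; isolated intact NB cells are returned separately
#' as single-CTC candidates.  Fragments within the contact distance of a
#' member are tallied in `nFragmentsAttached` but never change cluster size
#' or label.
#'
#' @param cellset a classified [CellSet-class] (all `cellType` assigned)
#' @param edges contact graph from [buildContactGraph()]
#' @param minArea,minSolidity intact-cell criteria, see [checkIntact()]
#' @return list with `clusters` (one row per cluster: `eventId, clusterId,
#'   size, nNb, nImmune, nOther, label, nFragmentsAttached, qcPass,
#'   memberCellIds`) and `singles` (one row per isolated NB cell)
#' @export
callClusters <- function(cellset, edges, minArea = 30, minSolidity = 0.85) {
  tab <- cellData(cellset)
  emptyClusters <- data.frame(eventId = character(), clusterId = integer(),
                              size = integer(), nNb = integer(),
                              nImmune = integer(), nOther = integer(),
                              label = character(),
                              nFragmentsAttached = integer(),
                              qcPass = logical(), memberCellIds = character(),
                              stringsAsFactors = FALSE)
  emptySingles <- data.frame(eventId = character(), cellId = integer(),
                             stringsAsFactors = FALSE)
  if (!nrow(tab)) return(list(clusters = emptyClusters, singles = emptySingles))
  if (any(is.na(tab$cellType)))
    stop("cells must be classified before cluster calling")

  intact <- checkIntact(cellset, minArea, minSolidity)
  eligible <- tab$cellId[!tab$isFragment & tab$cellType != "FRAGMENT" & intact]
  fragments <- tab$cellId[tab$isFragment | tab$cellType == "FRAGMENT"]

  g <- igraph::make_empty_graph(n = length(eligible), directed = FALSE)
  igraph::V(g)$name <- as.character(eligible)
  e <- edges[edges$from %in% eligible & edges$to %in% eligible, , drop = FALSE]
  if (nrow(e))
    g <- igraph::add_edges(g, as.character(rbind(e$from, e$to)))
  comp <- if (length(eligible)) igraph::components(g)$membership else integer()

  typeOf <- function(id) tab$cellType[match(id, tab$cellId)]
  clusters <- list(); singles <- list(); cid <- 0L
  for (m in unique(comp)) {
    ids <- eligible[comp == m]
    ty <- typeOf(ids)
    nNb <- sum(ty == "NB")
    if (length(ids) == 1L) {
      if (nNb == 1L)
        singles[[length(singles) + 1L]] <-
          data.frame(eventId = cellset@eventId, cellId = ids,
                     stringsAsFactors = FALSE)
      next
    }
    if (nNb < 1L) next
    cid <- cid + 1L
    nImmune <- sum(ty == "IMMUNE")
    nOther <- sum(ty %in% c("OTHER_DN", "OTHER_DP"))
    attached <- unique(c(
      edges$to[edges$from %in% ids & edges$to %in% fragments],
      edges$from[edges$to %in% ids & edges$from %in% fragments]))
    clusters[[cid]] <- data.frame(
      eventId = cellset@eventId, clusterId = cid,
      size = length(ids), nNb = nNb, nImmune = nImmune, nOther = nOther,
      label = if (nImmune + nOther == 0L) "HOMOTYPIC" else "HETEROTYPIC",
      nFragmentsAttached = length(attached), qcPass = TRUE,
      memberCellIds = paste(ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(clusters = if (length(clusters)) do.call(rbind, clusters) else emptyClusters,
       singles = if (length(singles)) do.call(rbind, singles) else emptySingles)
}

#' Cluster-size distribution
#'
#' Counts and within-label percentages of cluster sizes, split by
#' homotypic/heterotypic label; percentages sum to 100 per label.
#'
#' @param calls data.frame of cluster calls (`size`, `label` columns)
#' @return data.frame `label, size, n, pct`
#' @export
sizeDistribution <- function(calls) {
  if (is.null(calls) || !nrow(calls))
    return(data.frame(label = character(), size = integer(), n = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (lb in unique(calls$label)) {
    sz <- calls$size[calls$label == lb]
    tb <- table(sz)
    out[[lb]] <- data.frame(label = lb, size = as.integer(names(tb)),
                            n = as.integer(tb),
                            pct = 100 * as.integer(tb) / length(sz),
                            stringsAsFactors = FALSE)
  }
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

#' Write cluster calls as CSV
#'
#' Columns `event_id, size, n_nb, n_immune, n_other, label, qc_pass,
#' n_fragments_attached`.
#'
#' @param calls cluster-call data.frame
#' @param path output path
#' @export
writeClusterCalls <- function(calls, path) {
  out <- data.frame(event_id = calls$eventId, size = calls$size,
                    n_nb = calls$nNb, n_immune = calls$nImmune,
                    n_other = calls$nOther, label = calls$label,
                    qc_pass = calls$qcPass,
                    n_fragments_attached = calls$nFragmentsAttached)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
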