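# Nucleus segmentation, marker quantification, threshold calibration and
# marker-logic cell typing.
#
# Nuclei are connected components of the DAPI foreground, split by a
# distance-transform watershed when one component holds several local maxima
# at the configured minimum separation.  The cell body is recovered by
# growing each nucleus outwards (up to a fixed dilation radius) over the
# brightfield foreground, with competing nuclei partitioning shared pixels
# by nearest-nucleus assignment (a Voronoi split).  Per-cell marker
# intensity is the median over the cell body for the surface markers
# (GD2, CD45) and over the nucleus for the nuclear stain (DAPI): cells in
# contact share mask boundaries to within a pixel, and the median is
# insensitive to the handful of boundary pixels that can land on the wrong
# side of a contact, where the mean is not.

#' Segment the cells of one event
#'
#' @param event an [EventImage-class]
#' @param eventId identifier (defaults to the truth id when present)
#' @param minContrast passed to [foregroundMask()]
#' @param dilationRadius maximum distance (px) a cell body extends from its
#'   nucleus
#' @param minPeakSep minimum separation (px) of distance-map maxima before a
#'   DAPI component is split into two nuclei
#' @param wsTolerance watershed tolerance (intensity units of the distance
#'   map)
#' @param minNucleusSize smallest accepted nucleus, px
#' @param minFragmentSize smallest DAPI-negative brightfield object kept as
#'   a fragment placeholder, px
#' @return a [CellSet-class] (possibly empty)
#' @export
segmentCells <- function(event, eventId = NULL, minContrast = 40,
                         dilationRadius = 4, minPeakSep = 6, wsTolerance = 1,
                         minNucleusSize = 4, minFragmentSize = 4) {
  if (is.null(eventId)) {
    tr <- eventTruth(event)
    eventId <- if (!is.null(tr) && nrow(tr$cells)) tr$cells$eventId[1] else "E1"
  }
  dim <- dim(event@channels$BF)
  bf <- foregroundMask(event@channels$BF, minContrast)
  dp <- foregroundMask(event@channels$DAPI, minContrast)
  fg <- bf | dp

  cells <- list()
  nucLabel <- matrix(0L, dim[1], dim[2])
  nNuc <- 0L
  if (any(dp)) {
    dmap <- EBImage::distmap(dp)
    ws <- EBImage::watershed(dmap, tolerance = wsTolerance,
                             ext = max(1L, floor(minPeakSep / 2)))
    ws <- as.integer(ws)
    sz <- tabulate(ws)
    keep <- which(sz >= minNucleusSize)
    for (l in keep) {
      nNuc <- nNuc + 1L
      nucLabel[ws == l] <- nNuc
    }
  }

  assigned <- matrix(0L, dim[1], dim[2])
  if (nNuc > 0) {
    # distance of every pixel to each nucleus; nearest nucleus wins within
    # the dilation radius (Voronoi partition of the foreground)
    fgIdx <- which(fg)
    # each nucleus competes only for pixels of its own foreground component:
    # distinct touching cells remain distinct components (their boundaries
    # are close but not fused), so this clips every cell body to the true
    # object it belongs to
    fgLab <- EBImage::bwlabel(fg)
    nucComp <- vapply(seq_len(nNuc), function(i) {
      comps <- fgLab[nucLabel == i]
      comps <- comps[comps > 0]
      if (!length(comps)) return(0L)
      as.integer(names(which.max(table(comps))))
    }, integer(1))
    D <- vapply(seq_len(nNuc), function(i) {
      dm <- EBImage::distmap(nucLabel != i)
      d <- dm[fgIdx]
      d[fgLab[fgIdx] != nucComp[i]] <- Inf
      d
    }, numeric(length(fgIdx)))
    D <- matrix(D, nrow = length(fgIdx))
    nearest <- max.col(-D, ties.method = "first")
    dmin <- D[cbind(seq_along(fgIdx), nearest)]
    ok <- is.finite(dmin) & dmin <= dilationRadius
    assigned[fgIdx[ok]] <- nearest[ok]
    # a nucleus always belongs to its own cell, even if noise fractured the
    # foreground component it sits in
    assigned[nucLabel > 0L] <- nucLabel[nucLabel > 0L]
  }

  for (i in seq_len(nNuc)) {
    px <- which(assigned == i)
    nuc <- which(nucLabel == i)
    cells[[length(cells) + 1L]] <- list(
      cellId = length(cells) + 1L, pixels = px, nucleusPixels = nuc,
      isFragment = FALSE,
      gd2 = stats::median(event@channels$GD2[px]),
      cd45 = stats::median(event@channels$CD45[px]),
      dapi = stats::median(event@channels$DAPI[nuc]),
      area = length(px), solidity = maskSolidity(px, dim),
      cellType = NA_character_)
  }

  # DAPI-negative brightfield material left over after cell assignment
  leftover <- bf & (assigned == 0L)
  if (any(leftover)) {
    lab <- EBImage::bwlabel(leftover)
    sz <- tabulate(lab)
    for (l in which(sz >= minFragmentSize)) {
      px <- which(lab == l)
      cells[[length(cells) + 1L]] <- list(
        cellId = length(cells) + 1L, pixels = px, nucleusPixels = integer(),
        isFragment = TRUE,
        gd2 = stats::median(event@channels$GD2[px]),
        cd45 = stats::median(event@channels$CD45[px]),
        dapi = stats::median(event@channels$DAPI[px]),
        area = length(px), solidity = maskSolidity(px, dim),
        cellType = NA_character_)
    }
  }

  cellSet(eventId, dim, cells, pixelSize = event@pixelSize)
}

#' Calibrate marker-positivity thresholds from negative controls
#'
#' Each threshold is `mean + kSigma * SD` of the per-cell marker intensity
#' of the appropriate marker-negative population in control events: GD2 over
#' all nucleated control cells (controls carry no tumour cells), CD45 and
#' DAPI over the DAPI-negative fragment population (the only CD45-negative
#' objects a leukocyte control contains).  Degenerate (zero-variance)
#' controls yield `mean + epsilon` with a warning.
#'
#' @param controlEvents list of [EventImage-class] from a negative control
#' @param kSigma standard-deviation multiplier (default 3)
#' @param epsilon offset used when the control variance is zero
#' @param ... passed to [segmentCells()]
#' @return a [MarkerThresholds-class]
#' @export
calibrateThresholds <- function(controlEvents, kSigma = 3, epsilon = 1e-6,
                                ...) {
  sets <- lapply(controlEvents, segmentCells, ...)
  tab <- do.call(rbind, lapply(sets, cellData))
  if (is.null(tab) || !nrow(tab)) stop("no objects segmented in controls")
  cellsTab <- tab[!tab$isFragment, , drop = FALSE]
  fragTab <- tab[tab$isFragment, , drop = FALSE]
  if (nrow(cellsTab) < 50)
    stop(sprintf("need >= 50 segmented control cells, got %d", nrow(cellsTab)))
  if (nrow(fragTab) < 5)
    stop("controls must contain DAPI-negative fragments to calibrate CD45/DAPI thresholds")
  cut <- function(v, what) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("degenerate %s controls (zero variance); using mean + epsilon", what))
      return(mean(v) + epsilon)
    }
    mean(v) + kSigma * s
  }
  markerThresholds(gd2Pos = cut(cellsTab$gd2, "GD2"),
                   cd45Pos = cut(fragTab$cd45, "CD45"),
                   dapiPos = cut(fragTab$dapi, "DAPI"),
                   kSigma = kSigma)
}

#' Marker-logic cell classification
#'
#' Total over the eight marker combinations, with strict `>` positivity:
#' DAPI-negative objects are fragments regardless of surface markers;
#' among DAPI-positive cells, GD2+/CD45- is a neuroblastoma cell,
#' GD2-/CD45+ an immune cell, GD2-/CD45- a double-negative other cell and
#' GD2+/CD45+ a double-positive other cell (retained as non-tumour by
#' default; set `reclassifyDoublePositive` to count GD2+/CD45+ cells as
#' tumour cells instead).
#'
#' @param cell list or one-row data.frame with `gd2`, `cd45`,
#'   `dapi`
#' @param thresholds a [MarkerThresholds-class]
#' @param reclassifyDoublePositive treat GD2+/CD45+ cells as NB?
#' @return one of `"NB"`, `"IMMUNE"`, `"OTHER_DN"`, `"OTHER_DP"`,
#'   `"FRAGMENT"`
#' @export
classifyCell <- function(cell, thresholds, reclassifyDoublePositive = FALSE) {
  gd2 <- cell$gd2 > thresholds@gd2Pos
  cd45 <- cell$cd45 > thresholds@cd45Pos
  dapi <- cell$dapi > thresholds@dapiPos
  if (!isTRUE(dapi)) return("FRAGMENT")
  if (gd2 && !cd45) return("NB")
  if (!gd2 && cd45) return("IMMUNE")
  if (!gd2 && !cd45) return("OTHER_DN")
  if (reclassifyDoublePositive) "NB" else "OTHER_DP"
}

#' @describeIn classifyCell classify every object of a [CellSet-class],
#'   returning the set with `cellType` filled in
#' @param cellset a [CellSet-class]
#' @export
classifyCells <- function(cellset, thresholds, reclassifyDoublePositive = FALSE) {
  cellset@cells <- lapply(cellset@cells, function(cl) {
    cl$cellType <- classifyCell(cl, thresholds, reclassifyDoublePositive)
    cl
  })
  cellset
}

#' Typing accuracy against ground truth
#'
#' Matches each ground-truth nucleated cell of each event to the segmented
#' cell with the largest mask overlap and scores the fraction whose
#' assigned type equals the truth type.  Unmatched truth cells count as
#' errors.
#'
#' @param events list of [EventImage-class] with truth
#' @param cellsets list of classified [CellSet-class], same order
#' @return fraction in `[0, 1]` (NA when no truth cells exist)
#' @export
typingAccuracy <- function(events, cellsets) {
  good <- 0L; total <- 0L
  for (i in seq_along(events)) {
    tr <- eventTruth(events[[i]])
    if (is.null(tr)) next
    cs <- cellsets[[i]]
    truthCells <- tr$cells[tr$cells$type != "FRAGMENT", , drop = FALSE]
    for (j in seq_len(nrow(truthCells))) {
      total <- total + 1L
      tpx <- which(tr$labelMap == truthCells$cellId[j])
      best <- 0L; bestOv <- 0L
      for (k in seq_along(cs@cells)) {
        ov <- sum(cs@cells[[k]]$pixels %in% tpx)
        if (ov > bestOv) { bestOv <- ov; best <- k }
      }
      if (best > 0L &&
          identical(cs@cells[[best]]$cellType, truthCells$type[j]))
        good <- good + 1L
    }
  }
  if (total == 0L) return(NA_real_)
  good / total
}
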