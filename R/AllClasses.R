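#' @import methods
NULL

CHANNELS <- c("BF", "GD2", "CD45", "DAPI")
CELL_TYPES <- c("NB", "IMMUNE", "OTHER_DN", "OTHER_DP", "FRAGMENT")

#' Event composition specification
#'
#' Ground-truth composition of one synthetic imaging-flow-cytometry event:
#' how many neuroblastoma (GD2+/CD45-) cells, immune (GD2-/CD45+) cells,
#' other double-negative nucleated cells and DAPI-negative fragments it
#' contains.  An event with two or more nucleated cells is a ground-truth
#' cluster candidate; events carry at most eight nucleated cells by default,
#' the largest cluster size observed in neuroblastoma blood samples.
#'
#' @slot nNb number of neuroblastoma cells
#' @slot nImmune number of immune cells
#' @slot nOther number of GD2-/CD45- nucleated cells
#' @slot nFragments number of DAPI-negative fragments
#' @export
setClass("CompositionSpec",
  representation(nNb = "integer", nImmune = "integer",
                 nOther = "integer", nFragments = "integer"),
  validity = function(object) {
    v <- c(object@nNb, object@nImmune, object@nOther, object@nFragments)
    if (any(is.na(v)) || any(v < 0L))
      return("all composition counts must be non-negative integers")
    TRUE
  })

#' @param nNb,nImmune,nOther,nFragments non-negative integer counts
#' @rdname CompositionSpec-class
#' @export
compositionSpec <- function(nNb = 0, nImmune = 0, nOther = 0, nFragments = 0) {
  new("CompositionSpec", nNb = as.integer(nNb), nImmune = as.integer(nImmune),
      nOther = as.integer(nOther), nFragments = as.integer(nFragments))
}

#' Acquisition noise model for synthetic events
#'
#' Additive background, Poisson-like shot noise (Gaussian with standard
#' deviation `shotNoiseScale * sqrt(signal)`), additive Gaussian read noise
#' and a per-cell brightness coefficient of variation.  At all-zero noise the
#' rendered channels are piecewise constant, so segmentation must recover the
#' rendered masks exactly.
#'
#' @slot backgroundLevel intensity units added to every pixel of every channel
#' @slot shotNoiseScale dimensionless scale of signal-dependent noise
#' @slot gaussianSd additive Gaussian noise standard deviation (intensity units)
#' @slot intensityCv coefficient of variation of per-cell marker brightness
#' @export
setClass("NoiseModel",
  representation(backgroundLevel = "numeric", shotNoiseScale = "numeric",
                 gaussianSd = "numeric", intensityCv = "numeric"),
  validity = function(object) {
    v <- c(object@backgroundLevel, object@shotNoiseScale,
           object@gaussianSd, object@intensityCv)
    if (any(is.na(v)) || any(v < 0)) return("noise parameters must be >= 0")
    TRUE
  })

#' @param backgroundLevel,shotNoiseScale,gaussianSd,intensityCv see slots
#' @rdname NoiseModel-class
#' @export
noiseModel <- function(backgroundLevel = 10, shotNoiseScale = 0.1,
                       gaussianSd = 2, intensityCv = 0.1) {
  new("NoiseModel", backgroundLevel = backgroundLevel,
      shotNoiseScale = shotNoiseScale, gaussianSd = gaussianSd,
      intensityCv = intensityCv)
}

#' @rdname NoiseModel-class
#' @export
zeroNoise <- function() noiseModel(0, 0, 0, 0)

#' One imaging-flow-cytometry event
#'
#' Aligned 2D intensity images for the four channels (BF, GD2, CD45, DAPI),
#' the physical pixel size, and — for synthetic events — the ground truth:
#' a per-pixel label map plus a per-cell table of type and centroid.
#'
#' @slot channels named list of numeric matrices, one per channel, same shape
#' @slot pixelSize micrometres per pixel
#' @slot truth list with elements `labelMap`, `cells`, `spec` (empty for
#'   events of unknown composition, e.g. read from disk without truth)
#' @export
setClass("EventImage",
  representation(channels = "list", pixelSize = "numeric", truth = "list"),
  validity = function(object) {
    if (!identical(sort(names(object@channels)), sort(CHANNELS)))
      return(sprintf("channels must be exactly {%s}",
                     paste(CHANNELS, collapse = ", ")))
    dims <- lapply(object@channels, dim)
    if (length(unique(dims)) != 1L)
      return("all channel images must have identical dimensions")
    if (any(vapply(object@channels, function(m) any(m < 0), logical(1))))
      return("channel intensities must be non-negative")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  })

#' @param channels,pixelSize,truth see slots
#' @rdname EventImage-class
#' @export
eventImage <- function(channels, pixelSize = 0.5, truth = list()) {
  new("EventImage", channels = channels[CHANNELS], pixelSize = pixelSize,
      truth = truth)
}

#' Marker positivity thresholds
#'
#' Per-channel intensity cut-offs above which a cell is called positive for
#' GD2, CD45 or DAPI, together with the k-sigma multiplier used when the
#' thresholds were calibrated from negative controls.
#'
#' @slot gd2Pos,cd45Pos,dapiPos intensity thresholds (strict `>` positivity)
#' @slot kSigma multiplier applied to the control standard deviation
#' @export
setClass("MarkerThresholds",
  representation(gd2Pos = "numeric", cd45Pos = "numeric",
                 dapiPos = "numeric", kSigma = "numeric"),
  validity = function(object) {
    if (any(c(object@gd2Pos, object@cd45Pos, object@dapiPos) <= 0))
      return("all thresholds must be > 0")
    TRUE
  })

#' @param gd2Pos,cd45Pos,dapiPos,kSigma see slots
#' @rdname MarkerThresholds-class
#' @export
markerThresholds <- function(gd2Pos, cd45Pos, dapiPos, kSigma = 3) {
  new("MarkerThresholds", gd2Pos = gd2Pos, cd45Pos = cd45Pos,
      dapiPos = dapiPos, kSigma = kSigma)
}

#' Segmented cells of one event
#'
#' The result of nucleus segmentation on a single event: a list of cell
#' objects, each holding its nucleus and cell pixel sets (linear indices into
#' the event image), per-channel median intensities, shape descriptors and —
#' after classification — the assigned cell type.  DAPI-negative brightfield
#' objects are carried as fragment placeholders.
#'
#' @slot eventId event identifier
#' @slot imageDim dimensions of the source event image
#' @slot pixelSize micrometres per pixel
#' @slot cells list; each element has fields `cellId`, `pixels`,
#'   `nucleusPixels`, `isFragment`, `gd2`, `cd45`, `dapi`,
#'   `area`, `solidity`, `cellType`
#' @export
setClass("CellSet",
  representation(eventId = "character", imageDim = "integer",
                 pixelSize = "numeric", cells = "list"),
  validity = function(object) {
    for (cl in object@cells) {
      need <- c("cellId", "pixels", "nucleusPixels", "isFragment",
                "gd2", "cd45", "dapi", "area", "solidity",
                "cellType")
      if (!all(need %in% names(cl)))
        return("each cell must carry the full field set")
      if (!all(cl$nucleusPixels %in% cl$pixels))
        return("nucleus mask must be contained in the cell mask")
    }
    px <- unlist(lapply(object@cells, `[[`, "pixels"))
    if (anyDuplicated(px)) return("cell masks within an event must be disjoint")
    TRUE
  })

#' @param eventId,imageDim,pixelSize,cells see slots
#' @rdname CellSet-class
#' @export
cellSet <- function(eventId, imageDim, cells, pixelSize = 0.5) {
  new("CellSet", eventId = as.character(eventId),
      imageDim = as.integer(imageDim), pixelSize = pixelSize, cells = cells)
}

#' Cohort-level summary
#'
#' Aggregated per-sample counts: detection rates, totals, the
#' homotypic/heterotypic split, per-mL normalised values and the results of
#' the cohort statistical tests.
#'
#' @slot nPatients,nWithCtcs,nWithClusters,nClustersNoCtcs integer counts
#' @slot pctWithCtcs,pctWithClusters integer-rounded detection percentages
#' @slot totalSingles,totalClusters integer totals over the cohort
#' @slot totalHomotypic,totalHeterotypic cluster-composition totals (NA when
#'   per-sample splits are unavailable and no published split is supplied)
#' @slot pctHomotypic,pctHeterotypic percentages at 1-decimal half-up rounding
#' @slot perSample data.frame with per-mL values per patient
#' @slot tests list of statistical test results
#' @slot notes character vector recording fallbacks taken
#' @export
setClass("CohortSummary",
  representation(nPatients = "integer", nWithCtcs = "integer",
                 nWithClusters = "integer", nClustersNoCtcs = "integer",
                 pctWithCtcs = "numeric", pctWithClusters = "numeric",
                 totalSingles = "numeric", totalClusters = "numeric",
                 totalHomotypic = "numeric", totalHeterotypic = "numeric",
                 pctHomotypic = "numeric", pctHeterotypic = "numeric",
                 perSample = "data.frame", tests = "list",
                 notes = "character"))

setMethod("show", "CompositionSpec", function(object) {
  cat(sprintf("CompositionSpec: %d NB + %d immune + %d other cells, %d fragment(s)\n",
              object@nNb, object@nImmune, object@nOther, object@nFragments))
})

setMethod("show", "EventImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("EventImage %dx%d px (%.2f um/px), channels: %s\n",
              d[1], d[2], object@pixelSize,
              paste(names(object@channels), collapse = ", ")))
  if (length(object@truth))
    cat(sprintf("  ground truth: %d object(s)\n", nrow(object@truth$cells)))
})

setMethod("show", "MarkerThresholds", function(object) {
  cat(sprintf("MarkerThresholds (k = %g): GD2 > %.3f, CD45 > %.3f, DAPI > %.3f\n",
              object@kSigma, object@gd2Pos, object@cd45Pos, object@dapiPos))
})

setMethod("show", "CellSet", function(object) {
  n <- sum(!vapply(object@cells, `[[`, logical(1), "isFragment"))
  f <- length(object@cells) - n
  cat(sprintf("CellSet for event '%s': %d nucleated cell(s), %d fragment(s)\n",
              object@eventId, n, f))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d patients\n", object@nPatients))
  cat(sprintf("  CTC-positive:     %d/%d (%g%%)\n", object@nWithCtcs,
              object@nPatients, object@pctWithCtcs))
  cat(sprintf("  cluster-positive: %d/%d (%g%%)\n", object@nWithClusters,
              object@nPatients, object@pctWithClusters))
  cat(sprintf("  total clusters: %g (singles: %g)\n", object@totalClusters,
              object@totalSingles))
  if (!is.na(object@totalHeterotypic))
    cat(sprintf("  heterotypic: %g (%g%%), homotypic: %g (%g%%)\n",
                object@totalHeterotypic, object@pctHeterotypic,
                object@totalHomotypic, object@pctHomotypic))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' Accessors for event and cell containers
#'
#' @param x an `EventImage` or `CellSet`
#' @param channel one of `"BF"`, `"GD2"`, `"CD45"`, `"DAPI"`
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EventImage", function(x) names(x@channels))

#' @rdname accessors
#' @export
setGeneric("channelImage", function(x, channel) standardGeneric("channelImage"))
#' @rdname accessors
#' @export
setMethod("channelImage", "EventImage", function(x, channel) {
  channel <- match.arg(channel, CHANNELS)
  x@channels[[channel]]
})

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "EventImage", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CellSet", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("eventTruth", function(x) standardGeneric("eventTruth"))
#' @rdname accessors
#' @export
setMethod("eventTruth", "EventImage", function(x)
  if (length(x@truth)) x@truth else NULL)

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setMethod("nCells", "CellSet", function(x)
  sum(!vapply(x@cells, `[[`, logical(1), "isFragment")))

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @describeIn accessors one row per segmented object (cells and fragments)
#' with per-channel means, area, solidity and assigned type
#' @export
setMethod("cellData", "CellSet", function(x) {
  if (!length(x@cells))
    return(data.frame(eventId = character(), cellId = integer(),
                      isFragment = logical(), area = numeric(),
                      solidity = numeric(), gd2 = numeric(),
                      cd45 = numeric(), dapi = numeric(),
                      cellType = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x@cells, function(cl) {
    data.frame(eventId = x@eventId, cellId = cl$cellId,
               isFragment = cl$isFragment, area = cl$area,
               solidity = cl$solidity, gd2 = cl$gd2,
               cd45 = cl$cd45, dapi = cl$dapi,
               cellType = if (is.null(cl$cellType)) NA_character_ else cl$cellType,
               stringsAsFactors = FALSE)
  }))
})

#' @rdname accessors
#' @param i cell index within the set
#' @export
setGeneric("cellMask", function(x, i) standardGeneric("cellMask"))

#' @describeIn accessors logical mask matrix of one cell
#' @export
setMethod("cellMask", "CellSet", function(x, i) {
  m <- matrix(FALSE, x@imageDim[1], x@imageDim[2])
  m[x@cells[[i]]$pixels] <- TRUE
  m
})
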