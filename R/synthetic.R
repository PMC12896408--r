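# Synthetic imaging-flow-cytometry event generator.
#
# Events emulate what an ImageStream-class instrument records for one object
# passing the camera: a small multi-channel image holding one cell or one
# tight group of cells.  Cells are rendered as axis-aligned ellipses with a
# concentric nucleus at 60% linear scale; members of a multi-cell event are
# packed so that neighbouring cell boundaries sit within the contact
# distance, which makes ground-truth contact unambiguous.  Marker logic:
# neuroblastoma cells carry GD2 signal and no CD45, immune cells the
# converse, "other" nucleated cells neither; every nucleated cell has DAPI
# signal over its nucleus and brightfield signal over its whole body;
# fragments are small DAPI-negative brightfield-only blobs.

#' Default per-channel signal amplitudes for synthetic events
#'
#' Intensity added on top of the background for positive objects, in the
#' arbitrary units the generator works in.
#' @export
defaultAmplitudes <- function() c(BF = 80, GD2 = 150, CD45 = 150, DAPI = 150)

#' Generate one synthetic event image
#'
#' Renders the requested composition on a square canvas and records full
#' ground truth (per-pixel label map and per-cell table).  Cells of a
#' multi-cell event are placed so each new cell touches an already placed
#' one (pixel gap at most the contact tolerance), giving one connected
#' ground-truth group.  Fragments are attached to a cell when
#' `attachFragments` is `TRUE`, otherwise placed well clear of all cells.
#'
#' @param spec a [CompositionSpec-class]
#' @param noise a [NoiseModel-class]
#' @param seed integer seed; `NULL` uses the current RNG stream (as when
#'   called from [generateSample()])
#' @param canvas image height/width in pixels
#' @param pixelSize micrometres per pixel
#' @param cellDiameter range the two ellipse axes are drawn from, px
#' @param nucleusScale linear scale of the concentric nucleus
#' @param fragmentDiameter axis range for fragment blobs, px
#' @param amplitudes named vector of per-channel signal amplitudes
#' @param attachFragments place fragments in contact with a cell?
#' @param fragmentGd2Prob probability a fragment carries GD2 signal
#' @param gap continuous boundary gap aimed for between touching cells, px
#' @param borderMargin minimum clearance from the canvas border, px
#' @param eventId identifier stored in the truth table
#' @return an [EventImage-class] with ground truth
#' @export
generateEvent <- function(spec, noise = noiseModel(), seed = NULL,
                          canvas = c(64, 64), pixelSize = 0.5,
                          cellDiameter = c(10, 12), nucleusScale = 0.6,
                          fragmentDiameter = c(3, 5),
                          amplitudes = defaultAmplitudes(),
                          attachFragments = TRUE, fragmentGd2Prob = 0,
                          gap = 1, borderMargin = 2, eventId = "E1") {
  stopifnot(is(spec, "CompositionSpec"), is(noise, "NoiseModel"))
  if (!is.null(seed))
    return(withr::with_seed(seed, generateEvent(spec, noise, NULL, canvas,
      pixelSize, cellDiameter, nucleusScale, fragmentDiameter, amplitudes,
      attachFragments, fragmentGd2Prob, gap, borderMargin, eventId)))

  dim <- as.integer(rep(canvas, length.out = 2))
  types <- c(rep("NB", spec@nNb), rep("IMMUNE", spec@nImmune),
             rep("OTHER_DN", spec@nOther))
  nCell <- length(types)
  if (nCell > 1) types <- sample(types)

  placed <- list()  # each: pixels, center, ax (semi-axes), type, isFragment
  centerOf <- function(p) p$center

  placeFirst <- function(ax) {
    cen <- dim[2:1] / 2 + stats::runif(2, -1.5, 1.5)
    px <- renderEllipse(cen[1], cen[2], ax[1], ax[2], dim)
    if (!length(px)) stop("canvas overflow: cannot place first cell")
    rc <- idxToCoord(px, dim)
    if (min(rc) <= borderMargin || max(rc[, 1]) > dim[1] - borderMargin ||
        max(rc[, 2]) > dim[2] - borderMargin)
      stop("canvas overflow: first cell touches the border margin")
    list(center = cen, pixels = px)
  }

  inBounds <- function(px) {
    if (!length(px)) return(FALSE)
    rc <- idxToCoord(px, dim)
    min(rc[, 1]) > borderMargin && max(rc[, 1]) <= dim[1] - borderMargin &&
      min(rc[, 2]) > borderMargin && max(rc[, 2]) <= dim[2] - borderMargin
  }

  # place an ellipse touching an existing object: choose an angle, start at
  # continuous-boundary gap `gap`, then step towards the anchor until the
  # pixel-mask distance drops to the contact tolerance without overlap
  placeTouching <- function(ax, allPixels, contactTarget = 1.5) {
    anchorOrder <- order(vapply(placed, function(p)
      sum((p$center - dim[2:1] / 2)^2), numeric(1)))
    thetas <- seq(0, 2 * pi, length.out = 25)[-25] + stats::runif(1, 0, pi / 12)
    for (ai in anchorOrder) {
      anchor <- placed[[ai]]
      # prefer angles that keep the packing compact (centre-ward first)
      score <- vapply(thetas, function(th) {
        cen <- anchor$center + (radiusAtAngle(anchor$ax[1], anchor$ax[2], th) +
                                  radiusAtAngle(ax[1], ax[2], th + pi) + gap) *
          c(cos(th), sin(th))
        sum((cen - dim[2:1] / 2)^2)
      }, numeric(1))
      for (th in thetas[order(score)]) {
        u <- c(cos(th), sin(th))
        d0 <- radiusAtAngle(anchor$ax[1], anchor$ax[2], th) +
          radiusAtAngle(ax[1], ax[2], th + pi) + gap
        best <- NULL
        for (s in seq(0, gap + 1, by = 0.25)) {
          cen <- anchor$center + (d0 - s) * u
          px <- renderEllipse(cen[1], cen[2], ax[1], ax[2], dim)
          if (!inBounds(px)) next
          if (any(px %in% allPixels)) break
          dmin <- maskMinDistance(px, anchor$pixels, dim)
          if (is.null(best) || dmin < best$d)
            best <- list(center = cen, pixels = px, d = dmin)
          if (dmin <= contactTarget) break
        }
        if (!is.null(best) && best$d <= contactTarget + 0.5)
          return(best)
      }
    }
    NULL
  }

  allPixels <- integer()
  for (k in seq_len(nCell)) {
    ax <- stats::runif(2, cellDiameter[1], cellDiameter[2]) / 2
    if (k == 1) {
      p <- placeFirst(ax)
    } else {
      p <- placeTouching(ax, allPixels)
      if (is.null(p))
        stop(sprintf("canvas overflow: cannot place cell %d of %d on a %dx%d canvas",
                     k, nCell, dim[1], dim[2]))
    }
    placed[[k]] <- list(center = p$center, pixels = p$pixels, ax = ax,
                        type = types[k], isFragment = FALSE)
    allPixels <- c(allPixels, p$pixels)
  }

  # fragments
  for (k in seq_len(spec@nFragments)) {
    ax <- stats::runif(2, fragmentDiameter[1], fragmentDiameter[2]) / 2
    p <- NULL
    if (attachFragments && nCell > 0) p <- placeTouching(ax, allPixels)
    if (is.null(p)) {
      for (try in seq_len(400)) {
        cen <- c(stats::runif(1, borderMargin + ax[1] + 1, dim[2] - borderMargin - ax[1]),
                 stats::runif(1, borderMargin + ax[2] + 1, dim[1] - borderMargin - ax[2]))
        px <- renderEllipse(cen[1], cen[2], ax[1], ax[2], dim)
        if (!inBounds(px) || !length(px)) next
        clear <- if (length(allPixels))
          maskMinDistance(px, allPixels, dim) else Inf
        if ((attachFragments && nCell > 0 && clear <= 2 && clear > 0) ||
            ((!attachFragments || nCell == 0) && clear >= 6)) {
          p <- list(center = cen, pixels = px); break
        }
      }
    }
    if (is.null(p))
      stop("canvas overflow: cannot place fragment")
    placed[[length(placed) + 1L]] <- list(center = p$center, pixels = p$pixels,
                                          ax = ax, type = "FRAGMENT",
                                          isFragment = TRUE)
    allPixels <- c(allPixels, p$pixels)
  }

  # render channels
  bg <- noise@backgroundLevel
  ch <- lapply(CHANNELS, function(x) matrix(bg, dim[1], dim[2]))
  names(ch) <- CHANNELS
  labelMap <- matrix(0L, dim[1], dim[2])
  nuclei <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    labelMap[p$pixels] <- i
    f <- function() max(0.1, 1 + noise@intensityCv * stats::rnorm(1))
    ch$BF[p$pixels] <- bg + amplitudes[["BF"]] * f()
    if (p$isFragment) {
      if (fragmentGd2Prob > 0 && stats::runif(1) < fragmentGd2Prob)
        ch$GD2[p$pixels] <- bg + amplitudes[["GD2"]] * f()
      next
    }
    nuc <- renderEllipse(p$center[1], p$center[2],
                         p$ax[1] * nucleusScale, p$ax[2] * nucleusScale, dim)
    nuclei[[i]] <- nuc
    ch$DAPI[nuc] <- bg + amplitudes[["DAPI"]] * f()
    if (p$type == "NB") ch$GD2[p$pixels] <- bg + amplitudes[["GD2"]] * f()
    if (p$type == "IMMUNE") ch$CD45[p$pixels] <- bg + amplitudes[["CD45"]] * f()
  }

  if (noise@shotNoiseScale > 0 || noise@gaussianSd > 0) {
    n <- prod(dim)
    ch <- lapply(ch, function(m) {
      m <- m + stats::rnorm(n, 0, noise@gaussianSd) +
        stats::rnorm(n, 0, 1) * noise@shotNoiseScale * sqrt(pmax(m, 0))
      pmax(m, 0)
    })
  }

  cells <- do.call(rbind, lapply(seq_along(placed), function(i) {
    p <- placed[[i]]
    rc <- idxToCoord(p$pixels, dim)
    data.frame(eventId = eventId, cellId = i, type = p$type,
               centroidX = mean(rc[, 2]) - 1, centroidY = mean(rc[, 1]) - 1,
               area = length(p$pixels), stringsAsFactors = FALSE)
  }))

  eventImage(ch, pixelSize = pixelSize,
             truth = list(labelMap = labelMap, cells = cells, spec = spec,
                          nuclei = nuclei))
}

truthCategory <- function(nNb, nImmune, nOther) {
  nonNb <- nImmune + nOther
  ifelse(nNb == 1 & nonNb == 0, "single_ctc",
    ifelse(nNb >= 2 & nonNb == 0, "homotypic",
      ifelse(nNb >= 1 & nonNb >= 1, "heterotypic", "non_ctc")))
}

#' Generate a synthetic blood sample
#'
#' Draws `nEvents` events i.i.d. from a categorical distribution over
#' composition templates and renders each one.  The returned truth table
#' records the drawn template and composition per event plus the derived
#' category (single CTC, homotypic cluster, heterotypic cluster, or
#' non-CTC), so downstream calls can be checked against ground truth.
#'
#' @param nEvents number of events to draw
#' @param templates list of [CompositionSpec-class] objects
#' @param freqs template probabilities; must sum to 1 within 1e-9
#' @param volumeMl sample blood volume in mL (> 0)
#' @param noise a [NoiseModel-class]
#' @param seed integer seed; identical seeds give identical samples
#' @param ... passed to [generateEvent()]
#' @return list with `events` (list of [EventImage-class]), `truth`
#'   (per-event data.frame), `totals` (named single/homotypic/heterotypic
#'   counts) and `volumeMl`
#' @export
generateSample <- function(nEvents, templates, freqs, volumeMl = 5,
                           noise = noiseModel(), seed = 1, ...) {
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("template frequencies must sum to 1 (within 1e-9)")
  if (length(freqs) != length(templates))
    stop("freqs and templates must have equal length")
  if (volumeMl <= 0) stop("volumeMl must be positive")
  withr::with_seed(seed, {
    draw <- sample.int(length(templates), nEvents, replace = TRUE, prob = freqs)
    events <- vector("list", nEvents)
    rows <- vector("list", nEvents)
    for (i in seq_len(nEvents)) {
      sp <- templates[[draw[i]]]
      id <- sprintf("E%04d", i)
      events[[i]] <- generateEvent(sp, noise, seed = NULL, eventId = id, ...)
      rows[[i]] <- data.frame(eventId = id, templateIdx = draw[i],
                              nNb = sp@nNb, nImmune = sp@nImmune,
                              nOther = sp@nOther, nFragments = sp@nFragments,
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth$category <- truthCategory(truth$nNb, truth$nImmune, truth$nOther)
    truth$clusterSize <- with(truth, ifelse(category %in% c("homotypic", "heterotypic"),
                                            nNb + nImmune + nOther, NA_integer_))
    totals <- c(single = sum(truth$category == "single_ctc"),
                homotypic = sum(truth$category == "homotypic"),
                heterotypic = sum(truth$category == "heterotypic"))
    list(events = events, truth = truth, totals = totals, volumeMl = volumeMl)
  })
}

#' Generate a negative-control sample
#'
#' Emulates a healthy-volunteer control run: only immune cells and
#' DAPI-negative fragments, no GD2 signal above background.  Used to
#' calibrate marker-positivity thresholds and the single-cell object-area
#' distribution.  Fragments are placed detached so every control object is a
#' single-cell-scale object.
#'
#' @param nEvents number of control events (at least 50)
#' @param noise a [NoiseModel-class]
#' @param seed integer seed
#' @param ... passed to [generateEvent()]
#' @return list as from [generateSample()]
#' @export
generateControlSample <- function(nEvents, noise = noiseModel(), seed = 1, ...) {
  if (nEvents < 50)
    stop("control samples need at least 50 events to calibrate thresholds")
  templates <- list(compositionSpec(nImmune = 1),
                    compositionSpec(nImmune = 1, nFragments = 1),
                    compositionSpec(nFragments = 1))
  generateSample(nEvents, templates, c(0.55, 0.30, 0.15), volumeMl = 1,
                 noise = noise, seed = seed, attachFragments = FALSE, ...)
}

#' Write / read events as multi-page TIFF
#'
#' One 32-bit float page per channel in the fixed order BF, GD2, CD45, DAPI;
#' intensities are stored divided by `scale`.  Channel order, pixel size and
#' scale are recorded in a JSON sidecar (`<stem>.json`) because the TIFF
#' writer does not persist a description tag for float data.
#'
#' @param event an [EventImage-class]
#' @param path output path (`.tif`)
#' @param scale intensity divisor used to map to the unit range
#' @return `path`, invisibly
#' @export
writeEventTIFF <- function(event, path, scale = 65535) {
  pages <- lapply(event@channels[CHANNELS], function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(channels = CHANNELS, pixel_size = event@pixelSize,
               intensity_scale = scale)
  jsonlite::write_json(meta, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEventTIFF
#' @export
readEventTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- sub("\\.tiff?$", ".json", path)
  channels <- CHANNELS; px <- 0.5; scale <- 65535
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channels <- meta$channels; px <- meta$pixel_size
    scale <- meta$intensity_scale
  }
  ch <- lapply(pages, function(p) p * scale)
  names(ch) <- channels
  eventImage(ch, pixelSize = px)
}

#' Write per-cell ground truth as CSV
#'
#' Columns `event_id, cell_id, type, centroid_x, centroid_y` with 0-based
#' pixel coordinates, one row per rendered object across all events.
#'
#' @param events list of [EventImage-class] with truth
#' @param path output CSV path
#' @export
writeEventTruth <- function(events, path) {
  rows <- do.call(rbind, lapply(events, function(e) {
    tr <- eventTruth(e)
    if (is.null(tr)) return(NULL)
    tr$cells
  }))
  out <- data.frame(event_id = rows$eventId, cell_id = rows$cellId,
                    type = rows$type, centroid_x = rows$centroidX,
                    centroid_y = rows$centroidY)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
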