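# Candidate selection: object-level features, the object-area gate that
# isolates events larger than a single cell, and ranking by GD2 expression.

#' Compute object-level features for an event
#'
#' The object mask is the union of the brightfield and DAPI foregrounds,
#' restricted to the largest connected component plus any component lying
#' within the contact distance of it (so loosely attached material stays
#' with the main object while stray debris elsewhere on the canvas does
#' not).  A blank event is flagged empty and excluded downstream.
#'
#' @param event an [EventImage-class]
#' @param eventId identifier used in the output (defaults to the truth id
#'   when present)
#' @param contactDistance pixels; components within this distance of the
#'   largest one are included
#' @param minContrast passed to [foregroundMask()]
#' @return one-row data.frame: `eventId, empty, objectArea, objectAreaUm2,
#'   totalGd2, totalCd45, totalDapi`
#' @export
computeObjectFeatures <- function(event, eventId = NULL, contactDistance = 2,
                                  minContrast = 40) {
  if (is.null(eventId)) {
    tr <- eventTruth(event)
    eventId <- if (!is.null(tr) && nrow(tr$cells)) tr$cells$eventId[1] else "E1"
  }
  bf <- foregroundMask(event@channels$BF, minContrast)
  dp <- foregroundMask(event@channels$DAPI, minContrast)
  fg <- bf | dp
  empty <- data.frame(eventId = eventId, empty = TRUE,
                      objectArea = NA_real_, objectAreaUm2 = NA_real_,
                      totalGd2 = NA_real_, totalCd45 = NA_real_,
                      totalDapi = NA_real_, stringsAsFactors = FALSE)
  if (!any(fg)) return(empty)
  lab <- EBImage::bwlabel(fg)
  sz <- tabulate(lab)
  main <- which.max(sz)
  dim <- dim(lab)
  mainIdx <- which(lab == main)
  keep <- main
  for (l in setdiff(seq_along(sz), main)) {
    if (sz[l] == 0) next
    if (maskMinDistance(which(lab == l), mainIdx, dim) <= contactDistance)
      keep <- c(keep, l)
  }
  idx <- which(matrix(lab %in% keep, dim[1], dim[2]))
  data.frame(eventId = eventId, empty = FALSE,
             objectArea = length(idx),
             objectAreaUm2 = length(idx) * event@pixelSize^2,
             totalGd2 = sum(event@channels$GD2[idx]),
             totalCd45 = sum(event@channels$CD45[idx]),
             totalDapi = sum(event@channels$DAPI[idx]),
             stringsAsFactors = FALSE)
}

#' @describeIn computeObjectFeatures features for a list of events, one row
#'   each
#' @param events list of [EventImage-class]
#' @param ... passed on to `computeObjectFeatures`
#' @export
objectFeatures <- function(events, ...) {
  do.call(rbind, lapply(seq_along(events), function(i) {
    computeObjectFeatures(events[[i]], ...)
  }))
}

#' Area-gate policy
#'
#' How the "larger than a single cell" area threshold is resolved: either a
#' percentile of the single-cell object-area distribution measured on
#' negative-control events (default, 99th percentile) or an absolute area.
#'
#' @param mode `"percentile_of_controls"` or `"absolute"`
#' @param percentile percentile in (0, 100] used in control mode
#' @param absoluteArea area threshold in px^2 used in absolute mode
#' @export
areaGatePolicy <- function(mode = c("percentile_of_controls", "absolute"),
                           percentile = 99, absoluteArea = NULL) {
  mode <- match.arg(mode)
  if (mode == "percentile_of_controls") {
    stopifnot(percentile > 0, percentile <= 100)
  } else if (is.null(absoluteArea) || absoluteArea <= 0) {
    stop("absolute mode requires a positive absoluteArea")
  }
  structure(list(mode = mode, percentile = percentile,
                 absoluteArea = absoluteArea), class = "areaGatePolicy")
}

#' Resolve the object-area threshold
#'
#' In control mode the threshold is the order statistic at index
#' `ceiling(percentile/100 * n)` of the sorted non-empty control object
#' areas (empirical, no interpolation), requiring at least 50 control
#' objects; in absolute mode it is the configured value.
#'
#' @param controlFeatures data.frame from [objectFeatures()] on control
#'   events (ignored in absolute mode)
#' @param policy an [areaGatePolicy()]
#' @return threshold in px^2
#' @export
resolveAreaThreshold <- function(controlFeatures, policy = areaGatePolicy()) {
  if (policy$mode == "absolute") return(policy$absoluteArea)
  areas <- controlFeatures$objectArea[!controlFeatures$empty]
  if (length(areas) < 50)
    stop(sprintf("need >= 50 control objects to resolve the area gate, got %d",
                 length(areas)))
  s <- sort(areas)
  th <- s[ceiling(policy$percentile / 100 * length(s))]
  if (th <= 0) stop("resolved area threshold must be positive")
  th
}

#' Gate events on object area
#'
#' Returns the identifiers of events whose object area strictly exceeds the
#' threshold, preserving input order — the population "larger than a single
#' cell" that cluster calling inspects.
#'
#' @param features data.frame from [objectFeatures()]
#' @param threshold area threshold in px^2 (> 0)
#' @return character vector of event ids
#' @export
areaGate <- function(features, threshold) {
  stopifnot(threshold > 0)
  if (!nrow(features)) return(character())
  sel <- !features$empty & features$objectArea > threshold
  features$eventId[sel]
}

#' Rank candidate events by GD2 expression
#'
#' Stable descending sort on total GD2 intensity, ties broken by event id
#' ascending — the order in which candidates would be reviewed.
#'
#' @param candidates data.frame with `eventId` and `totalGd2`
#' @return the reordered data.frame
#' @export
rankByGD2 <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  candidates[order(-candidates$totalGd2, candidates$eventId), , drop = FALSE]
}
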