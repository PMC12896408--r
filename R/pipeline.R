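# Pipeline glue: configuration, the end-to-end run (simulate/read -> object
# features -> area gate -> rank -> segment & type -> cluster calls ->
# sample summary), and report writing.

#' Pipeline configuration
#'
#' All tunable parameters with their documented defaults.  The object
#' round-trips losslessly through YAML ([writePipelineConfig()] /
#' [readPipelineConfig()]).
#'
#' @param seed RNG seed for the whole run
#' @param nEvents number of events simulated per sample
#' @param volumeMl blood volume the simulated sample represents, mL
#' @param templates list of template definitions, each a list with fields
#'   `nb`, `immune`, `other`, `fragments`, `freq`
#' @param noise list `background`, `shot`, `gaussian`, `cv`
#' @param canvas canvas side, px
#' @param pixelSize micrometres per pixel
#' @param cellDiameter cell axis range, px
#' @param gate list `mode`, `percentile`, `absoluteArea`
#' @param kSigma threshold-calibration multiplier
#' @param contactDistance contact-graph distance, px
#' @param qc list `minArea`, `minSolidity`
#' @param nControlEvents control events simulated for calibration
#' @param eventDir optional directory of event TIFFs to analyse instead of
#'   simulating
#' @param outDir optional output directory for CSV/JSON reports
#' @export
pipelineConfig <- function(seed = 1, nEvents = 200, volumeMl = 5,
                           templates = defaultTemplates(),
                           noise = list(background = 10, shot = 0.1,
                                        gaussian = 2, cv = 0.1),
                           canvas = 96, pixelSize = 0.5,
                           cellDiameter = c(10, 12),
                           gate = list(mode = "percentile_of_controls",
                                       percentile = 99, absoluteArea = NULL),
                           kSigma = 3, contactDistance = 2,
                           qc = list(minArea = 30, minSolidity = 0.85),
                           nControlEvents = 120, eventDir = NULL,
                           outDir = NULL) {
  structure(list(seed = seed, nEvents = nEvents, volumeMl = volumeMl,
                 templates = templates, noise = noise, canvas = canvas,
                 pixelSize = pixelSize, cellDiameter = cellDiameter,
                 gate = gate, kSigma = kSigma,
                 contactDistance = contactDistance, qc = qc,
                 nControlEvents = nControlEvents, eventDir = eventDir,
                 outDir = outDir),
            class = "pipelineConfig")
}

#' Default simulated-sample composition templates
#'
#' A mixture of single CTCs, homotypic and heterotypic clusters from two to
#' eight cells, immune cells and fragment-only debris, approximating a
#' cluster-rich patient sample.
#' @export
defaultTemplates <- function() {
  list(
    list(nb = 1, immune = 0, other = 0, fragments = 0, freq = 0.25),
    list(nb = 0, immune = 1, other = 0, fragments = 0, freq = 0.20),
    list(nb = 2, immune = 0, other = 0, fragments = 0, freq = 0.10),
    list(nb = 3, immune = 0, other = 0, fragments = 0, freq = 0.04),
    list(nb = 1, immune = 1, other = 0, fragments = 0, freq = 0.16),
    list(nb = 1, immune = 2, other = 0, fragments = 0, freq = 0.08),
    list(nb = 1, immune = 1, other = 1, fragments = 1, freq = 0.05),
    list(nb = 1, immune = 5, other = 0, fragments = 0, freq = 0.03),
    list(nb = 2, immune = 4, other = 2, fragments = 0, freq = 0.02),
    list(nb = 1, immune = 0, other = 0, fragments = 1, freq = 0.04),
    list(nb = 0, immune = 0, other = 0, fragments = 1, freq = 0.03))
}

templateSpecs <- function(templates) {
  list(specs = lapply(templates, function(t)
         compositionSpec(t$nb, t$immune, t$other, t$fragments)),
       freqs = vapply(templates, `[[`, numeric(1), "freq"))
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig`
#' @param path YAML file path
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipelineConfig, raw[intersect(names(raw),
                                               names(formals(pipelineConfig)))])
  cfg
}

#' Run the full detection pipeline on one sample
#'
#' Simulates (or reads) the sample's events, calibrates marker thresholds
#' and the object-area gate on a simulated negative control, computes
#' object features, gates and GD2-ranks cluster candidates, segments and
#' types the cells of every event, calls clusters on gated events, and
#' summarises the sample.  Single CTCs are counted across all events
#' (isolated intact NB cells); clusters only among area-gated candidates,
#' mirroring the manual workflow's candidate selection.  Deterministic for
#' a fixed seed.  When `outDir` is set, writes `cluster_calls.csv`,
#' `sample_summary.csv`, `report.json` and `report.txt`.
#'
#' @param config a [pipelineConfig()]
#' @return list: `counts` (singles/homotypic/heterotypic), `clusters`,
#'   `singles`, `sizeDistribution`, `perMl`, `thresholds` used, `candidates`
#'   (GD2-ranked), `truth` totals when available
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  noise <- noiseModel(config$noise$background, config$noise$shot,
                      config$noise$gaussian, config$noise$cv)
  truthTotals <- NULL
  if (is.null(config$eventDir)) {
    tpl <- templateSpecs(config$templates)
    sample <- generateSample(config$nEvents, tpl$specs, tpl$freqs,
                             volumeMl = config$volumeMl, noise = noise,
                             seed = config$seed,
                             canvas = config$canvas,
                             pixelSize = config$pixelSize,
                             cellDiameter = config$cellDiameter)
    events <- sample$events
    truthTotals <- sample$totals
  } else {
    files <- sort(list.files(config$eventDir, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (!length(files)) stop("event_gating: no TIFF events in eventDir")
    events <- lapply(files, readEventTIFF)
    names(events) <- sub("\\.tiff?$", "", basename(files))
  }
  eventIds <- vapply(seq_along(events), function(i) {
    tr <- eventTruth(events[[i]])
    if (!is.null(tr) && nrow(tr$cells)) tr$cells$eventId[1]
    else if (!is.null(names(events)) && nzchar(names(events)[i])) names(events)[i]
    else sprintf("E%04d", i)
  }, character(1))

  # negative control: threshold calibration + area gate
  control <- generateControlSample(config$nControlEvents, noise = noise,
                                   seed = childSeed(config$seed, 1),
                                   canvas = config$canvas,
                                   pixelSize = config$pixelSize,
                                   cellDiameter = config$cellDiameter)
  thresholds <- tryCatch(
    calibrateThresholds(control$events, kSigma = config$kSigma),
    error = function(e) stop("cell_typing: ", conditionMessage(e)))
  policy <- areaGatePolicy(config$gate$mode,
                           percentile = config$gate$percentile,
                           absoluteArea = config$gate$absoluteArea)
  controlFeatures <- objectFeatures(control$events)
  areaThreshold <- tryCatch(resolveAreaThreshold(controlFeatures, policy),
                            error = function(e) stop("event_gating: ",
                                                     conditionMessage(e)))

  features <- do.call(rbind, lapply(seq_along(events), function(i)
    computeObjectFeatures(events[[i]], eventId = eventIds[i],
                          contactDistance = config$contactDistance)))
  gated <- areaGate(features, areaThreshold)
  candidates <- rankByGD2(features[features$eventId %in% gated, , drop = FALSE])

  # segment and type every event; call clusters on gated candidates
  allClusters <- list(); allSingles <- list()
  for (i in seq_along(events)) {
    cs <- segmentCells(events[[i]], eventId = eventIds[i])
    cs <- classifyCells(cs, thresholds)
    edges <- buildContactGraph(cs, config$contactDistance)
    calls <- callClusters(cs, edges, minArea = config$qc$minArea,
                          minSolidity = config$qc$minSolidity)
    if (eventIds[i] %in% gated && nrow(calls$clusters))
      allClusters[[length(allClusters) + 1L]] <- calls$clusters
    if (nrow(calls$singles))
      allSingles[[length(allSingles) + 1L]] <- calls$singles
  }
  clusters <- if (length(allClusters)) do.call(rbind, allClusters) else
    callClusters(cellSet("none", c(2L, 2L), list()),
                 data.frame(from = integer(), to = integer(),
                            dist = numeric()))$clusters
  singles <- if (length(allSingles)) do.call(rbind, allSingles) else
    data.frame(eventId = character(), cellId = integer())

  counts <- c(single = nrow(singles),
              homotypic = sum(clusters$label == "HOMOTYPIC"),
              heterotypic = sum(clusters$label == "HETEROTYPIC"))
  volumeMl <- if (is.null(config$eventDir)) config$volumeMl else config$volumeMl
  perMl <- c(singles_per_ml = roundHalfUp(perML(counts[["single"]], volumeMl), 1),
             clusters_per_ml = roundHalfUp(
               perML(counts[["homotypic"]] + counts[["heterotypic"]], volumeMl), 1))

  report <- list(
    nEvents = length(events),
    thresholds = list(gd2 = thresholds@gd2Pos, cd45 = thresholds@cd45Pos,
                      dapi = thresholds@dapiPos, kSigma = thresholds@kSigma,
                      objectArea = areaThreshold),
    counts = counts, perMl = perMl,
    sizeDistribution = sizeDistribution(clusters),
    clusters = clusters, singles = singles, candidates = candidates,
    truth = truthTotals, seed = config$seed)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeClusterCalls(clusters, file.path(config$outDir, "cluster_calls.csv"))
    utils::write.csv(
      data.frame(n_events = report$nEvents, volume_ml = volumeMl,
                 n_single_ctcs = counts[["single"]],
                 n_homotypic = counts[["homotypic"]],
                 n_heterotypic = counts[["heterotypic"]],
                 singles_per_ml = perMl[["singles_per_ml"]],
                 clusters_per_ml = perMl[["clusters_per_ml"]]),
      file.path(config$outDir, "sample_summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(nEvents = report$nEvents, thresholds = report$thresholds,
           counts = as.list(counts), perMl = as.list(perMl),
           seed = report$seed),
      file.path(config$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("events analysed:        %d", report$nEvents),
      sprintf("GD2 threshold:          %.3f", thresholds@gd2Pos),
      sprintf("CD45 threshold:         %.3f", thresholds@cd45Pos),
      sprintf("DAPI threshold:         %.3f", thresholds@dapiPos),
      sprintf("object-area threshold:  %.1f px^2", areaThreshold),
      sprintf("single CTCs:            %d", counts[["single"]]),
      sprintf("homotypic clusters:     %d", counts[["homotypic"]]),
      sprintf("heterotypic clusters:   %d", counts[["heterotypic"]]),
      sprintf("single CTCs / mL:       %.1f", perMl[["singles_per_ml"]]),
      sprintf("clusters / mL:          %.1f", perMl[["clusters_per_ml"]])),
      file.path(config$outDir, "report.txt"))
  }
  report
}
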