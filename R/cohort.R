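# Cohort-level aggregation: per-mL normalisation, detection rates, the
# homotypic/heterotypic split and the cohort statistical tests.

#' Per-millilitre normalisation
#'
#' Exact `count / volume`; report rendering rounds half-up to one decimal
#' (see [roundHalfUp()]), the precision cohort tables are printed at.
#'
#' @param count event count (vectorised)
#' @param volumeMl sample volume in mL, strictly positive
#' @export
perML <- function(count, volumeMl) {
  if (any(volumeMl <= 0)) stop("volumeMl must be strictly positive")
  count / volumeMl
}

#' Read a cohort table
#'
#' CSV with one row per patient sample.  Required columns: `patient_id`,
#' `stage` (Diagnosis/Relapse), `risk_group` (Low/Intermediate/High),
#' `status` (DOD/ADF/TD), `marrow_involved` (logical), `volume_ml`,
#' `n_single_ctcs`, `n_clusters`; optional: `ploidy` (`-` treated as
#' missing), `n_homotypic`, `n_heterotypic`.  Validation failures report
#' the offending rows.
#'
#' @param path CSV path
#' @return data.frame of typed sample records
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("patient_id", "stage", "risk_group", "status",
                "marrow_involved", "volume_ml", "n_single_ctcs", "n_clusters")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("cohort table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$patient_id))
    stop("duplicate patient_id values: ",
         paste(unique(tab$patient_id[duplicated(tab$patient_id)]), collapse = ", "))
  numCheck <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) || any(is.na(tab[[col]])))
      stop(sprintf("non-numeric or missing %s in row(s): %s", col,
                   paste(union(bad, which(is.na(tab[[col]]))), collapse = ", ")))
    v
  }
  tab$volume_ml <- numCheck("volume_ml")
  tab$n_single_ctcs <- numCheck("n_single_ctcs")
  tab$n_clusters <- numCheck("n_clusters")
  if (any(tab$volume_ml <= 0))
    stop("non-positive volume_ml in row(s): ",
         paste(which(tab$volume_ml <= 0), collapse = ", "))
  bad <- which(!tab$stage %in% c("Diagnosis", "Relapse"))
  if (length(bad))
    stop("invalid stage in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!tab$risk_group %in% c("Low", "Intermediate", "High"))
  if (length(bad))
    stop("invalid risk_group in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!tab$status %in% c("DOD", "ADF", "TD"))
  if (length(bad))
    stop("invalid status in row(s): ", paste(bad, collapse = ", "))
  tab$marrow_involved <- as.logical(tab$marrow_involved)
  if ("ploidy" %in% names(tab))
    tab$ploidy[tab$ploidy %in% c("-", "")] <- NA_character_
  for (col in c("n_homotypic", "n_heterotypic"))
    if (col %in% names(tab)) tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  if (all(c("n_homotypic", "n_heterotypic") %in% names(tab))) {
    both <- !is.na(tab$n_homotypic) & !is.na(tab$n_heterotypic)
    bad <- which(both & tab$n_homotypic + tab$n_heterotypic != tab$n_clusters)
    if (length(bad))
      stop("n_homotypic + n_heterotypic != n_clusters in row(s): ",
           paste(bad, collapse = ", "))
  }
  tab
}

#' Bundled neuroblastoma cohort table
#'
#' Path to (or the parsed content of) the 24-patient cohort table shipped
#' with the package: per-sample blood volume, single-CTC and CTC-cluster
#' counts with clinical annotations.
#'
#' @param parsed return the parsed data.frame instead of the file path?
#' @export
cohortFixture <- function(parsed = TRUE) {
  path <- system.file("extdata", "nb_cohort_table.csv", package = "ifcClusters",
                      mustWork = TRUE)
  if (parsed) readCohortTable(path) else path
}

#' Published cohort-level cluster-composition totals
#'
#' The cohort-wide heterotypic/homotypic cluster totals as published for
#' this cohort (per-sample splits were only shown graphically, so they
#' cannot be re-derived from the per-sample table); used to render
#' report-style composition percentages.
#'
#' @export
publishedClusterSplit <- function() {
  path <- system.file("extdata", "published_totals.csv",
                      package = "ifcClusters", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as.list(stats::setNames(tab$value, tab$quantity))
}

#' Cluster-composition percentages
#'
#' Heterotypic and homotypic percentages of total clusters at 1-decimal
#' half-up rounding, as rendered in cohort reports.
#'
#' @param nHeterotypic,nHomotypic cluster totals
#' @export
compositionPercentages <- function(nHeterotypic, nHomotypic) {
  total <- nHeterotypic + nHomotypic
  if (total <= 0) stop("no clusters to compute composition percentages from")
  c(heterotypic = roundHalfUp(100 * nHeterotypic / total, 1),
    homotypic = roundHalfUp(100 * nHomotypic / total, 1))
}

#' Summarise a cohort
#'
#' Detection counts use strict `> 0`; detection percentages are rounded to
#' integers, composition percentages to one decimal (half-up), per-mL
#' values to one decimal in the per-sample table.  Statistical tests: the
#' Spearman pairs (single CTCs vs heterotypic clusters; homotypic vs
#' heterotypic clusters) when per-sample splits are present, with a
#' recorded fallback to total clusters otherwise; Fisher's exact test on
#' homotypic-cluster presence against high-risk status when splits are
#' present; the chi-square test on cluster presence against
#' died-of-disease status (toxic deaths counted as non-DOD).
#'
#' @param records data.frame from [readCohortTable()]
#' @param publishedSplit optional list with `total_heterotypic` and
#'   `total_homotypic` used for composition percentages when per-sample
#'   splits are absent (see [publishedClusterSplit()])
#' @return a [CohortSummary-class]
#' @export
summarizeCohort <- function(records, publishedSplit = NULL) {
  if (!nrow(records)) stop("need at least one sample record")
  n <- nrow(records)
  withCtcs <- sum(records$n_single_ctcs > 0)
  withClusters <- sum(records$n_clusters > 0)
  noCtcs <- sum(records$n_clusters > 0 & records$n_single_ctcs == 0)
  totalClusters <- sum(records$n_clusters)
  totalSingles <- sum(records$n_single_ctcs)

  notes <- character()
  haveSplit <- all(c("n_homotypic", "n_heterotypic") %in% names(records)) &&
    !anyNA(records$n_homotypic) && !anyNA(records$n_heterotypic)
  if (haveSplit) {
    totalHomo <- sum(records$n_homotypic)
    totalHet <- sum(records$n_heterotypic)
  } else if (!is.null(publishedSplit)) {
    totalHomo <- publishedSplit$total_homotypic
    totalHet <- publishedSplit$total_heterotypic
    notes <- c(notes, "composition totals taken from published cohort-level split")
  } else {
    totalHomo <- NA_real_; totalHet <- NA_real_
  }
  if (!is.na(totalHet) && totalHet + totalHomo > 0) {
    pcts <- compositionPercentages(totalHet, totalHomo)
  } else pcts <- c(heterotypic = NA_real_, homotypic = NA_real_)

  perSample <- data.frame(
    patient_id = records$patient_id,
    singles_per_ml = roundHalfUp(perML(records$n_single_ctcs, records$volume_ml), 1),
    clusters_per_ml = roundHalfUp(perML(records$n_clusters, records$volume_ml), 1))

  tests <- list()
  if (haveSplit) {
    tests$spearman_singles_vs_heterotypic <-
      spearmanTest(records$n_single_ctcs, records$n_heterotypic)
    tests$spearman_homotypic_vs_heterotypic <-
      spearmanTest(records$n_homotypic, records$n_heterotypic)
    tests$fisher_homotypic_by_risk <- fisherExact2x2(table(
      factor(records$n_homotypic > 0, levels = c(TRUE, FALSE)),
      factor(records$risk_group == "High", levels = c(TRUE, FALSE))))
  } else {
    tests$spearman_singles_vs_clusters <-
      spearmanTest(records$n_single_ctcs, records$n_clusters)
    notes <- c(notes,
      "per-sample composition splits unavailable: Spearman computed on total clusters, Fisher test skipped")
  }
  chiTab <- table(factor(records$n_clusters > 0, levels = c(TRUE, FALSE)),
                  factor(records$status == "DOD", levels = c(TRUE, FALSE)))
  tests$chisq_clusters_by_survival <- tryCatch(chiSquareTest(chiTab),
                                               error = function(e) NULL)

  new("CohortSummary",
      nPatients = as.integer(n), nWithCtcs = as.integer(withCtcs),
      nWithClusters = as.integer(withClusters),
      nClustersNoCtcs = as.integer(noCtcs),
      pctWithCtcs = roundHalfUp(100 * withCtcs / n),
      pctWithClusters = roundHalfUp(100 * withClusters / n),
      totalSingles = totalSingles, totalClusters = totalClusters,
      totalHomotypic = as.numeric(totalHomo),
      totalHeterotypic = as.numeric(totalHet),
      pctHomotypic = unname(pcts["homotypic"]),
      pctHeterotypic = unname(pcts["heterotypic"]),
      perSample = perSample, tests = tests, notes = notes)
}
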