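test_that("the bundled cohort table parses into 24 typed records", {
  tab <- cohortFixture()
  expect_equal(nrow(tab), 24)
  p8 <- tab[tab$patient_id == 8, ]
  expect_equal(p8$volume_ml, 1.6)
  expect_equal(p8$n_single_ctcs, 0)
  expect_equal(p8$n_clusters, 0)
  expect_true(is.na(tab$ploidy[tab$patient_id == 2]))
  expect_true(all(tab$volume_ml > 0))
})

test_that("schema violations are reported with row context", {
  dir <- withr::local_tempdir()
  tab <- cohortFixture()

  noVol <- tab[, setdiff(names(tab), "volume_ml")]
  f1 <- file.path(dir, "novol.csv"); write.csv(noVol, f1, row.names = FALSE)
  expect_error(readCohortTable(f1), "volume_ml")

  dup <- rbind(tab, tab[1, ])
  f2 <- file.path(dir, "dup.csv"); write.csv(dup, f2, row.names = FALSE)
  expect_error(readCohortTable(f2), "duplicate")

  bad <- tab; bad$stage[3] <- "Remission"
  f3 <- file.path(dir, "stage.csv"); write.csv(bad, f3, row.names = FALSE)
  expect_error(readCohortTable(f3), "row\\(s\\): 3")

  badVol <- tab; badVol$volume_ml[5] <- "x"
  f4 <- file.path(dir, "vol.csv"); write.csv(badVol, f4, row.names = FALSE)
  expect_error(readCohortTable(f4), "volume_ml")
})

test_that("per-mL values reproduce the printed per-sample normalisation", {
  expect_equal(roundHalfUp(perML(725, 8.0), 1), 90.6)
  expect_equal(roundHalfUp(perML(654, 4.0), 1), 163.5)
  expect_equal(perML(0, 3.3), 0)
  expect_error(perML(5, 0), "positive")
  # every printed per-mL column entry of the fixture
  tab <- cohortFixture()
  expect_equal(roundHalfUp(perML(tab$n_single_ctcs, tab$volume_ml), 1),
               c(2.9, 0, 163.5, 0, 11.3, 6, 9.7, 0, 5.8, 77.8, 6.8, 130.5,
                 13.2, 5.8, 14.5, 17.6, 17.3, 0, 0, 0, 0, 0, 39, 30.7))
  expect_equal(roundHalfUp(perML(tab$n_clusters, tab$volume_ml), 1),
               c(0.1, 0, 11.8, 3, 39.4, 88.5, 0.1, 0, 2.2, 29.8, 0.7, 4.8,
                 0.9, 90.6, 1.8, 0.3, 0.7, 0, 0.7, 0, 0, 0.3, 9.1, 2.3))
})

test_that("cohort summaries aggregate detection counts and totals", {
  sm <- summarizeCohort(cohortFixture(), publishedSplit = publishedClusterSplit())
  expect_equal(sm@nPatients, 24L)
  expect_equal(sm@totalClusters, 2094)
  expect_equal(sm@nWithClusters, 19L)
  expect_equal(sm@nWithCtcs, 16L)
  expect_equal(sm@pctWithClusters, 79)
  expect_equal(sm@pctWithCtcs, 67)
  expect_equal(sm@nClustersNoCtcs, 3L)
  expect_equal(sm@pctHeterotypic, 93.9)
  expect_equal(sm@pctHomotypic, 6.1)
  # conservation: totals equal the per-sample sums
  expect_equal(sm@totalSingles, sum(cohortFixture()$n_single_ctcs))
  # the chi-square test on cluster presence vs survival is computable
  expect_false(is.null(sm@tests$chisq_clusters_by_survival))
  expect_true("spearman_singles_vs_clusters" %in% names(sm@tests))
  expect_match(paste(sm@notes, collapse = " "), "splits unavailable")
})

test_that("per-sample composition splits unlock the full test battery", {
  set.seed(11)
  rec <- data.frame(patient_id = 1:12,
                    stage = "Diagnosis",
                    risk_group = rep(c("High", "Low"), 6),
                    status = rep(c("DOD", "ADF"), each = 6),
                    marrow_involved = TRUE,
                    volume_ml = runif(12, 2, 9),
                    n_heterotypic = rpois(12, 8),
                    n_homotypic = rpois(12, 1))
  rec$n_clusters <- rec$n_heterotypic + rec$n_homotypic
  rec$n_single_ctcs <- rpois(12, 20)
  sm <- summarizeCohort(rec)
  expect_equal(sm@totalHeterotypic, sum(rec$n_heterotypic))
  expect_equal(sm@totalClusters, sum(rec$n_clusters))
  expect_equal(sm@pctHeterotypic + sm@pctHomotypic, 100, tolerance = 0.11)
  expect_true(all(c("spearman_singles_vs_heterotypic",
                    "spearman_homotypic_vs_heterotypic",
                    "fisher_homotypic_by_risk") %in% names(sm@tests)))
  f <- sm@tests$fisher_homotypic_by_risk
  expect_gte(f$p, 0); expect_lte(f$p, 1)
})

test_that("composition percentages render at one-decimal half-up precision", {
  pc <- compositionPercentages(1967, 127)
  expect_equal(unname(pc["heterotypic"]), 93.9)
  expect_equal(unname(pc["homotypic"]), 6.1)
  expect_error(compositionPercentages(0, 0), "no clusters")
})
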