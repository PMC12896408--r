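# ifcClusters

Detection and characterisation of circulating tumour cell (CTC) clusters in
neuroblastoma blood samples analysed by imaging flow cytometry.

Neuroblastoma tumours release CTCs into the bloodstream, where they can
travel as multicellular clusters — the entities most strongly implicated in
metastatic seeding.  Imaging flow cytometry records a multi-channel image of
every event, so cluster composition can be resolved cell by cell.  This
package is for researchers working with such data (or planning such
assays): it turns the manual screening workflow into an automated, fully
testable pipeline, and aggregates per-sample counts into cohort-level
statistics.

## The model

Cell identity follows three-marker logic on a per-cell basis, with
brightfield (BF) morphology as a quality screen:

* **NB cell**: GD2+ / CD45− / DAPI+
* **immune cell**: GD2− / CD45+ / DAPI+
* **other cell**: GD2− / CD45− / DAPI+ or GD2+ / CD45+ / DAPI+
* **fragment**: DAPI− (never counted as a cluster member)

A **cluster** is a connected group (contact graph of segmented, intact,
nucleated cells) with ≥ 2 members, at least one of which is an NB cell.
It is **homotypic** when all members are NB cells and **heterotypic**
otherwise.  Isolated NB cells are single-CTC candidates.  Positivity
thresholds are calibrated from negative controls as mean + 3·SD of the
marker-negative population; the "larger than a single cell" area gate that
prioritises cluster candidates is the 99th-percentile order statistic of
control single-cell object areas.  Per-sample counts normalise per mL and
the cohort summary runs Spearman rank correlation (exact permutation null
for n ≤ 9), Fisher's exact test (full hypergeometric-support enumeration)
and Pearson's chi-square, all significant at p ≤ 0.05.

Because no raw imaging data are deposited for this assay, the package
includes a synthetic event generator (`generateEvent()`,
`generateSample()`, `generateControlSample()`) that renders multi-channel
events with exhaustive ground truth — the basis of all image-level
validation.

## Worked example

Simulate a patient-like sample, run the full pipeline, and compare with the
generator's ground truth:

```r
library(ifcClusters)

cfg <- pipelineConfig(seed = 1, nEvents = 100)   # default mixed templates
rep <- runPipeline(cfg)

rep$counts
#>      single   homotypic heterotypic
#>          25          14          36
rep$truth        # generator ground truth for the same events
#>      single   homotypic heterotypic
#>          25          14          36
rep$perMl
#>  singles_per_ml clusters_per_ml
#>               5              10
rep$sizeDistribution
#>         label size  n       pct
#> 1 HETEROTYPIC    2 15 41.666667
#> 2 HETEROTYPIC    3 19 52.777778
#> 3 HETEROTYPIC    6  1  2.777778
#> 4 HETEROTYPIC    8  1  2.777778
#> 5   HOMOTYPIC    2 10 71.428571
#> 6   HOMOTYPIC    3  4 28.571429
```

The report lists every threshold actually used (marker cut-offs, object
area gate), the GD2-ranked candidate list, per-cluster calls and single-CTC
candidates.  At the default (noisy) settings the pipeline recovered this
sample's composition exactly; `vignettes/ctc-cluster-detection.Rmd`
explains each stage, its parameters and its limits.

Cohort-level summaries work from a per-sample table; the 24-patient table
shipped with the package reproduces the published detection rates:

```r
sm <- summarizeCohort(cohortFixture(), publishedSplit = publishedClusterSplit())
sm
#> CohortSummary: 24 patients
#>   CTC-positive:     16/24 (67%)
#>   cluster-positive: 19/24 (79%)
#>   total clusters: 2094 (singles: 2608)
#>   heterotypic: 1967 (93.9%), homotypic: 127 (6.1%)
```

A thin command-line wrapper with `simulate`, `gate`, `call`, `summarize`,
`stats` and `run-all` subcommands lives at
`inst/scripts/ifc-pipeline.R`.

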