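---
title: "Detecting circulating tumour cell clusters in imaging flow cytometry data"
author: "ifcClusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circulating tumour cell clusters in imaging flow cytometry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcClusters)
```

## Background

Neuroblastoma tumours shed circulating tumour cells (CTCs) into the
bloodstream, and these cells can travel as multicellular clusters.  Clusters
are of particular interest because, across cancer types, they are far more
efficient at seeding metastases than single CTCs.  Imaging flow cytometry
records a multi-channel image of every object ("event") passing the camera,
which makes it possible not just to count CTCs but to resolve the
composition of each cluster: a *homotypic* cluster consists exclusively of
tumour cells, while a *heterotypic* cluster combines at least one tumour
cell with other cell types such as leukocytes.

`ifcClusters` implements that analysis as an automated, testable pipeline.
Cell identity is read off three fluorescence channels plus brightfield:

| cell type            | GD2 | CD45 | DAPI |
|----------------------|-----|------|------|
| neuroblastoma (NB)   |  +  |  −   |  +   |
| immune               |  −  |  +   |  +   |
| other, double-neg.   |  −  |  −   |  +   |
| other, double-pos.   |  +  |  +   |  +   |
| fragment             |  ·  |  ·   |  −   |

GD2 is a disialoganglioside strongly expressed on neuroblastoma cells, CD45
is the pan-leukocyte antigen, and DAPI marks nuclei, separating cells from
anucleate fragments.  A cluster is at least one NB cell in contact with at
least one additional nucleated cell.  Double-positive (GD2+/CD45+) cells
are kept as non-tumour "other" cells by default — they may be tumour cells
engulfed by macrophages, and an optional flag (`reclassifyDoublePositive`)
reclassifies them as tumour cells for sensitivity analyses.

Because no raw imaging data are publicly deposited for this assay, the
package ships a synthetic event generator with exhaustive ground truth; all
image-level validation in the test suite runs against it.  Cohort-level
numbers are reproduced from the bundled 24-patient per-sample table.

## The synthetic event generator

`generateEvent()` renders one event: each nucleated cell is an axis-aligned
ellipse with a concentric nucleus at 60% linear scale; members of a
multi-cell event are packed so neighbouring boundaries sit within the
contact distance; fragments are small DAPI-negative brightfield-only blobs.
The generator records a per-pixel label map and a per-cell type table, so
every downstream stage can be scored exactly.

Key geometry defaults, and why:

* **Cell axis range 10–12 px** (5–6 µm at 0.5 µm/px, the scale of a
  lymphocyte-sized cell at 40× magnification).  The range is deliberately
  narrow: it keeps the single-cell object-area distribution
  (about 79–113 px²) disjoint from the two-cell distribution (≥ 157 px²),
  so an area gate calibrated on single-cell controls can in principle
  achieve perfect recall of multi-cell events.  A wider size range would
  overlap the two distributions and make the gate's recall limit a property
  of the geometry rather than of the method — configurable via
  `cellDiameter` for exactly that kind of experiment.
* **Nucleus at 60% linear scale**, giving nucleus areas well above the
  4-px segmentation floor and leaving a visible cytoplasmic rim.
* **Contact packing**: each new cluster member is placed touching an
  already placed member, with the pixel-mask gap driven to ≤ 2 px and
  overlap forbidden.  Ground-truth contact is therefore unambiguous, and
  an event's cells always form one connected group.
* **Canvas 96 px** in the pipeline defaults (64 px for single-cell work):
  eight touching cells of 12 px diameter need the headroom; the generator
  fails loudly ("canvas overflow") rather than cropping.
* **Fragments 3–5 px**, attached to a cell in patient-like samples and
  detached in control samples, optionally GD2-positive
  (`fragmentGd2Prob`).

The noise model has four parameters: a constant `backgroundLevel` per
channel, Gaussian read noise `gaussianSd`, signal-dependent shot noise
(`shotNoiseScale * sqrt(signal)`), and a per-cell brightness coefficient of
variation `intensityCv`.  Defaults (10, 2, 0.1, 0.1 in arbitrary intensity
units against signal amplitudes of 80–150) give clearly separable but not
noise-free images.  No published per-channel photometry exists for this
assay, so the amplitudes are free parameters of the simulation, not a
calibration to instrument units.  At `zeroNoise()` every channel is
piecewise constant and segmentation must be exact — that is the regime the
recovery tests use.

What the generator does *not* emulate: optics (no point-spread function,
no focus variation), spectral spillover between channels, realistic
brightfield texture, or flow dynamics.  Passing tests therefore demonstrate
the correctness of the rule logic and the robustness ordering of the
pipeline under increasing noise — they do not certify performance on real
instrument data, where foreground detection and threshold calibration
would face structured artefacts the simulation does not produce.

```{r example-event}
ev <- generateEvent(compositionSpec(nNb = 1, nImmune = 1), noiseModel(),
                    seed = 7)
ev
eventTruth(ev)$cells
```

## Candidate selection: the object-area gate

The screening workflow first finds events larger than a single cell, then
reviews them in order of decreasing GD2 signal.  `computeObjectFeatures()`
measures each event's object (the union of brightfield and DAPI
foregrounds, keeping the largest connected component plus anything within
the contact distance of it); `resolveAreaThreshold()` turns a policy into
a threshold; `areaGate()` applies it with a strict `>`; `rankByGD2()`
orders the survivors.

The default policy is the 99th percentile of the single-cell object-area
distribution measured on at least 50 negative-control events.  The
percentile is read as a plain order statistic (index
`ceiling(p/100 * n)` of the sorted areas, no interpolation), which keeps
the threshold reproducible bit-for-bit from the same controls.  An
absolute threshold (`areaGatePolicy("absolute", absoluteArea = ...)`) is
available when a fixed calibration is preferred.

One deliberate divergence from the manual workflow: the automated pipeline
segments and types **every** event, not only the gated ones, because
single-CTC counts (isolated NB cells) are part of the per-sample report
and small events never reach the gate.  The gate decides which events are
eligible for *cluster* calls, mirroring its screening role.

## Foreground detection and segmentation numerics

* Foreground per channel: Otsu's threshold on the min–max normalised
  image, accepted only if the resulting class contrast (foreground mean
  minus background mean) reaches `minContrast` (default 40 intensity
  units, i.e. about half the weakest signal amplitude).  The contrast
  floor is what rejects blank channels, where Otsu would otherwise split
  pure noise.  Components under 4 px are dropped and holes are filled
  label-wise (so two nearby objects are never bridged by hole filling).
* Nuclei: connected components of the DAPI foreground, split by a
  distance-transform watershed (`tolerance = 1`, neighbourhood
  `ext = minPeakSep/2` with `minPeakSep = 6` px) when a component holds
  several maxima — a merged pair of touching nuclei splits, a single
  elliptical nucleus does not.
* Cell bodies: each nucleus grows over the brightfield foreground up to a
  dilation radius of 4 px, competing nuclei partition contested pixels by
  nearest-nucleus distance (a Voronoi split), and a nucleus only competes
  for pixels of its own foreground component.  A cell's nucleus always
  belongs to its own body, even when noise fractures the foreground.
* Per-cell marker intensity is the **median** over the cell body for GD2
  and CD45 and over the nucleus for DAPI.  Touching cells share a mask
  boundary to within about a pixel, and a handful of boundary pixels can
  land on the wrong side of a contact; the median is completely
  insensitive to that, whereas a mean lets a single bled pixel flip a
  marker call when thresholds are tight.

## Threshold calibration

`calibrateThresholds()` uses a negative control (healthy-volunteer-like
events: immune cells and fragments only) and sets each positivity cut to
`mean + kSigma × SD` of the per-cell intensity of the marker-negative
population: GD2 over all nucleated control cells, CD45 and DAPI over the
DAPI-negative fragments — in a leukocyte control the fragments are the only
CD45-negative population available.  `kSigma = 3` is the conventional
negative-control gating margin; positivity is a strict `>`.  Zero-variance
(fully noiseless) controls fall back to `mean + epsilon` with a warning,
so the degenerate case stays well-defined.

## Cluster calling

`buildContactGraph()` connects two objects when the minimum distance
between their mask pixels is at most `contactDistance` (default 2 px;
"in contact" has no instrument definition, and 2 px absorbs segmentation
boundary jitter while rejecting clearly separated cells).
`checkIntact()` is the automated stand-in for visual brightfield
inspection: area ≥ 30 px² and solidity ≥ 0.85 keep debris-sized and
strongly concave objects out.  `callClusters()` then takes connected
components of the graph restricted to intact nucleated cells:

* a component is a **cluster** iff it has ≥ 2 members and ≥ 1 NB cell;
* it is **homotypic** iff every member is an NB cell — purity defines
  homotypy, so two NB cells plus an immune cell make one *heterotypic*
  cluster of three (the alternative reading, splitting such a component
  into a homotypic pair plus a contact, is not what a component-based
  caller can express and is documented as an open interpretation);
* components without an NB cell are discarded; isolated intact NB cells
  are reported separately as single-CTC candidates;
* fragments never join the graph; those within contact distance of a
  member are counted in `nFragmentsAttached` but never change size or
  label, since only nucleated cells count towards cluster composition.

## Cohort statistics

`summarizeCohort()` aggregates per-sample records: detection uses strict
`> 0`; detection percentages are integer-rounded; composition percentages
and per-mL values round half-up to one decimal — the conventions of the
printed per-sample table (for example 725 clusters in 8.0 mL prints as
90.6 clusters/mL).  Significance is declared at p ≤ 0.05.

The test cores are self-contained and oracle-checked:

* **Spearman** (`spearmanTest()`): correlation of midranks.  For n ≤ 9
  the two-sided p-value is exact — all n! permutations of one rank vector
  are enumerated and scored; above that a t-approximation with n − 2
  degrees of freedom is used (at the n = 9 cross-over the two agree to
  within 0.02 on random data, which the suite asserts).
* **Fisher's exact test** (`fisherExact2x2()`): two-sided p by full
  enumeration of the hypergeometric support with fixed margins, summing
  all tables at most as probable as the observed one (relative tolerance
  1e-7 on the comparison).
* **Chi-square** (`chiSquareTest()`): Pearson statistic, no continuity
  correction, explicit failure on zero expected counts.

The per-sample table only records total cluster counts; the per-patient
homotypic/heterotypic split was published graphically.  When per-sample
splits are absent, `summarizeCohort()` computes the Spearman correlation
on total clusters instead of heterotypic clusters, skips the Fisher test
on homotypic presence, and records both fallbacks in its `notes`; the
published cohort-level split (1967 heterotypic / 127 homotypic of 2094)
ships with the package (`publishedClusterSplit()`) for rendering
composition percentages.  The cohort association tests dichotomise to
presence/absence (homotypic-present × high-risk for Fisher;
cluster-present × died-of-disease, counting toxic deaths as non-DOD, for
the chi-square); the original contingency tables behind the published
p-values were not printed, so these constructions are documented defaults
rather than reproductions.

```{r cohort}
sm <- summarizeCohort(cohortFixture(), publishedSplit = publishedClusterSplit())
sm
```

## Validation strategy and problem sizes

The suite validates the pipeline at three levels:

1. **Rule level**: the cluster caller is compared against a brute-force
   transcription of the selection sentence over all 64 compositions with
   up to three cells of each type, and the marker logic over all eight
   marker-state combinations.
2. **Image level**: on zero-noise synthetic cohorts (five samples of 200
   events, mixed templates spanning single CTCs, homotypic and
   heterotypic clusters of two to eight cells, fragments and debris),
   called single-CTC/homotypic/heterotypic counts and the per-label size
   histograms must equal ground truth exactly.  Typing accuracy must be
   non-increasing along a Gaussian-noise ladder (SD 0, 10, 35 at signal
   amplitude 150) — under heavy noise the pipeline degrades, and it must
   degrade monotonically.  These sizes keep the full suite under a few
   minutes on a single core while leaving no stage untested at realistic
   event counts.
3. **Cohort level**: totals, detection rates, per-mL values and
   composition percentages recomputed from the bundled 24-patient table.

## Known limitations

* Validation is synthetic-image-based; no public raw data exist for this
  assay, and the generator's simplifications (no PSF, no spillover, flat
  brightfield) mean real-data performance is untested.
* GD2 can be downregulated after anti-GD2 immunotherapy or chemotherapy;
  a GD2-based tumour gate will under-detect such cells, synthetic or not.
* The proprietary instrument file format (.daf) is not read; events enter
  as multi-page TIFF (BF, GD2, CD45, DAPI) with a JSON sidecar for pixel
  size and channel order.
* Fragment provenance (platelets, cancer-associated fibroblasts) is not
  modelled — attached fragments are counted, not identified.
* The visual morphology review of the manual workflow is approximated by
  an area/solidity screen; unusual but genuine morphologies a reviewer
  would accept may be rejected, and vice versa.
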