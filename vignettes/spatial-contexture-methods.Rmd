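---
title: "Methods: spatial T-cell contexture analysis of multiplexed-immunofluorescence cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial T-cell contexture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and data model

`tmespat` analyzes per-cell tables exported from multiplexed-immunofluorescence
(mIF) imaging of tumor tissue: one row per segmented cell, with field-local
coordinates in micrometres, a tissue-compartment label (tumor epithelium,
stroma, or other), binary marker calls for CD3, CD8, FoxP3, Ki67 and
cytokeratin (CK), and a Granzyme-B (GrB) cytoplasmic mean intensity on a 0–1
scale. Upstream image processing — spectral unmixing, tissue and cell
segmentation, and the machine-learning marker classifier — is out of scope;
the package consumes its tabular output. Coordinates are taken to be in µm
with the origin at the top-left of each field; exports in pixels can be
rescaled with the `coord_scale` argument of `read_cell_table()`. Fields are
separate microscope images, so no distance ever crosses a field boundary.

## Phenotype gating

Cells are gated into ten categories: CD3+ (`T`), CD3+Ki67+ (`pT`),
CD3+CD8−FoxP3− (`Th`), CD3+CD8−FoxP3−Ki67+ (`pTh`), CD3+FoxP3+ (`Treg`),
CD3+FoxP3+Ki67+ (`pTreg`), CD3+CD8+ (`CD8T`), CD3+CD8+Ki67+ (`pCD8T`),
CD3+CD8+GrB+ (`aCD8T`), and CK+ (`Tumor`). Three modelling choices matter:

* **Memberships, not a partition.** A proliferating cytotoxic T cell belongs
  simultaneously to `T`, `pT`, `CD8T` and `pCD8T`. Density comparisons
  between a category and its subsets only make sense under this reading,
  and the subset lattice (`pTh ⊆ Th ⊆ T`, `aCD8T ⊆ CD8T`, …) is enforced by
  construction and re-checked by property tests over all 32 marker
  combinations.
* **GrB positivity** is a threshold on the cytoplasmic mean intensity,
  default cut-off 0.25 with an *inclusive* lower bound (intensity exactly at
  the cut-off is positive). The inclusivity is a package convention fixed
  for determinism.
* **Co-positive guards.** CK+CD3+ cells are rare segmentation artifacts;
  by default they are excluded both from `Tumor` (`tumor_excludes_cd3`) and
  from the T-cell categories (`t_excludes_ck`), and their count is recorded
  on the gated table. Both guards are flags, so either reading can be
  reproduced. A CD3+CD8+FoxP3+ cell qualifies for both `Treg` and `CD8T`;
  no mutual exclusion is invented beyond the marker definitions.

## Densities and fractions

Densities are reported per patient, category and compartment, in cells/mm².
The patient value pools the patient's fields: summed counts divided by
summed compartment area, *not* the mean of per-field densities. The pooled
ratio is area-weighted, invariant to unequal field sizes, and is pinned by a
test that also demonstrates it differs from the per-field mean. Compartment
areas (the denominators) are the areas of that compartment only — the
phrasing "cells/mm² in the epithelium" reads most naturally as
epithelium-area normalization — and cells in the "other" compartment
(necrosis, empty space) enter neither numerators nor denominators.
Marker-positive fractions (Ki67+ or GrB+ within `T`, `Th`, `Treg`, `CD8T`)
use the same pooling; a zero parent count yields a reason-coded missing
value, never a silent zero.

## Nearest-neighbor distance statistics

For a source category A and target category B within one field, each A-cell
contributes its Euclidean distance to the nearest B-cell. A cell present in
both categories is never its own neighbor (self-exclusion by cell identity);
if no other target exists the cell contributes a missing value. The
per-patient summary is the median of the per-cell distances pooled across
the patient's fields — pooling weights fields by how many cells they
contribute, unlike a median of field medians, and the convention is pinned
by tests. Distances from T cells to tumor cells restrict the *sources* to
non-intraepithelial cells (a T cell inside the epithelium is trivially close
to tumor cells), while targets are all CK+ cells in the field.

The cohort-level "overall nearest radius" is defined here as the median over
patients of the per-patient median CD3+→Tumor nearest distance. The exact
aggregation behind that figure is under-specified in the source material;
median-of-patient-medians is the construction used and labelled throughout.

The nearest-neighbor search is a chunked vectorized computation over the
full source×target distance structure; an O(n²) double-loop oracle in the
test suite confirms agreement within 1e-9 µm on random fixtures up to 300
cells, and a closed-form check recovers the Poisson nearest-distance mean
1/(2√λ) within 5%.

## Metric–expression association

Per-patient spatial metrics are correlated with gene expression for three
panels: the 20-gene immunologic constant of rejection (ICR) signature (with
the perforin entry mapped to HGNC symbol `PRF1` and the CD8 module expanded
to `CD8A`/`CD8B`), plus editable plain-text chemokine and cell–cell
interaction panels shipped with the package (bundled lists rather than live
database queries, so results do not drift with database versions). Pearson
correlation is the default for gene–metric analysis, Spearman for the
inter-metric matrix, following the respective analysis conventions; both are
available everywhere. Distance metrics are negated before correlation so
that a positive coefficient always means "higher expression, shorter
distance"; disabling the flag returns exactly the negated coefficients
(tested as an involution). Raw r, n and p are emitted; a Benjamini–Hochberg
utility is provided but never applied by default.

## Survival analysis

Patients are stratified at the cohort median of a metric: strictly above the
median is "high", ties at the median go to "low" (the literal reading of
"above the median"). Kaplan–Meier curves, the Mantel–Cox log-rank test and
Cox proportional-hazards models (Efron tie handling, Wald tests, 95% CI as
exp(β ± 1.96·se)) are computed via the `survival` package behind the module
interface; the test suite carries independent oracles (a hand product-limit
loop, an O−E table log-rank, and direct Efron partial-likelihood
maximization) so the wrappers are verified rather than trusted. Multivariate
models include exactly the covariates with univariate Wald p strictly below
0.05. Schoenfeld-residual diagnostics are attached to every fit but never
gate results. Collinearity and possible separation are flagged, never
silent.

## The synthetic cohort generator

The generator produces cohorts with the statistical structure the analysis
assumes, plus the planted ground truth needed for recovery tests:

* **Geometry.** 4 fields per patient, 669 × 500 µm (a 20× imaging field).
  The epithelium mask is a union of 8 random discs (radii 60–140 µm),
  rejection-sampled until the epithelium fraction reaches at least 0.30 —
  the field-selection rule of the emulated assay. Three small discs are
  punched out of the stroma as "other" tissue. Compartment areas are
  estimated by a jittered-grid integral (2 µm default), which is exactly
  unbiased for the true mask area; the same grid defines the reported
  field summaries.
* **Point processes.** Tumor cells are a homogeneous Poisson process on the
  epithelium mask (1500 cells/mm²). Each T-cell base subtype (helper,
  regulatory, cytotoxic) is a Thomas cluster process — Poisson parents
  (20/mm², drawn on a buffered box to avoid edge bias), Poisson offspring
  with 25 µm Gaussian spread — thinned to its compartment, with parents
  shared across subtypes so that subtype densities co-fluctuate within a
  field, giving the observed coordinated-infiltration correlation structure
  a generative counterpart. A configurable offset displaces regulatory-cell
  clusters from the shared parents, creating a planted, monotonically
  recoverable separation from cytotoxic cells.
* **Base conditions.** Helper T cells: 89.6 (epithelium) and 595.2 (stroma)
  cells/mm², the emulated cohort's medians; regulatory and cytotoxic
  subsets at similar, lower densities (40–160 cells/mm²); epithelial Ki67
  fractions 33.7% (helper) and 14.8% (cytotoxic), lower in stroma; GrB
  positivity highest in epithelial cytotoxic cells (35%). GrB intensities
  are drawn from a two-component Beta mixture whose components lie entirely
  below and at-or-above the 0.25 cut-off.
* **Latent immune activity.** One standard-normal factor per patient scales
  all T-cell intensities by exp(0.4 × latent), anchored so a latent-0
  (median) patient has exactly the base intensities, and drives every panel
  gene as baseline + b·latent + noise with b chosen for a population
  correlation of 0.7 — the planted association the correlation analysis
  must recover.
* **Outcomes.** The generator computes the configured spatial covariate
  (default: regulatory-to-helper nearest-neighbor distance) from its own
  cells with the package's real gating and distance code, median-splits it,
  and draws exponential proportional-hazards survival times with a planted
  hazard ratio of 0.281 for the high group (baseline hazard log(2)/4 per
  year, i.e. median survival 4 years; independent exponential censoring at
  0.12/year). Clinical covariates (age, sex, side, adjuvant treatment,
  stage, MSI, CMS) are drawn with realistic colon-cancer frequencies; the
  ICR class is the latent-factor tertile.

What the generator does *not* emulate: cell morphology and segmentation
error, marker-call misclassification, spatial anisotropy of real glands
(discs are isotropic), inter-field heterogeneity within a patient beyond
Poisson/Thomas noise, and non-proportional hazards. Passing recovery tests
therefore demonstrates the correctness of the analysis machinery under the
stated model, not the biological validity of any particular cohort.

## Numerical conventions and problem sizes

All tables are TSV (UTF-8, tab, "." decimal) with numerics serialized at 17
significant digits so write→read round-trips doubles exactly and repeated
runs are byte-identical (verified by hashed manifests). Medians use R's
default mid-mean convention for even counts. Correlation requires at least
3 complete pairs and defined variance; every undefined quantity carries a
reason code. The test suite exercises: 100 random spatial fixtures (up to
300 cells) against brute force; all 32 × 4 gating combinations; 500
simulated fields for intensity calibration (mean within 3 SE); correlation
recovery at n = 200 patients; Cox CI coverage and log-rank type-I error
over 1000 replicates at n = 100 with the planted-hazard recovery at
n = 500; and full pipelines at 5–30 patients. These sizes give stable
Monte-Carlo behavior for each property while keeping the default suite
quick to run.

## Known limitations

* The overall-nearest-radius construction is one of several defensible
  aggregations; alternatives (pooled cell-level median, mean of medians)
  are easy to compute from `summarize_patient_distances()` output but are
  not the labelled default.
* Density denominators use compartment area; if total tissue area is
  preferred, the long density table carries counts and areas so the
  alternative is a one-line recomputation.
* The Thomas-process intensity calibration is exact in expectation but
  clustered counts are overdispersed relative to Poisson; per-field counts
  fluctuate more than √mean.
* Competing risks, time-varying covariates and cut-point optimization are
  deliberately absent; the median split is the only stratification.
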